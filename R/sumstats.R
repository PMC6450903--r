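#' Read a GWAS summary-statistics table
#'
#' Reads a delimited text file of per-variant association results and maps
#' its columns onto the standard fields used throughout the package. Rows
#' with a missing or non-positive standard error, or a non-finite effect
#' estimate, are dropped and counted; duplicated variant identifiers are
#' reduced to their first occurrence with a warning.
#'
#' @param path Path to a delimited text file with a header row. The
#'   delimiter is detected by [data.table::fread()] (tab, comma or
#'   whitespace).
#' @param column_map Named character vector mapping standard field names to
#'   the column names in the file. Required fields: `variant_id`,
#'   `effect_allele`, `other_allele`, `beta`, `se`. Optional fields:
#'   `eaf`, `info`, `chrom`, `pos`.
#' @param quiet Suppress the message reporting dropped rows.
#'
#' @return A data frame with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se` and, when mapped, `eaf`, `info`,
#'   `chrom`, `pos`. The number of dropped rows is attached as attribute
#'   `n_dropped`.
#' @export
read_sumstats <- function(path,
                          column_map = c(variant_id = "SNP",
                                         effect_allele = "EA",
                                         other_allele = "OA",
                                         beta = "BETA",
                                         se = "SE"),
                          quiet = FALSE) {
  if (!file.exists(path)) {
    stop("summary-statistics file not found: ", path)
  }
  required <- c("variant_id", "effect_allele", "other_allele", "beta", "se")
  missing_fields <- setdiff(required, names(column_map))
  if (length(missing_fields)) {
    stop("column_map must name columns for: ",
         paste(missing_fields, collapse = ", "))
  }
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          showProgress = FALSE)
  if (nrow(dt) == 0L) {
    stop("empty summary-statistics file: ", path)
  }
  absent <- column_map[!column_map %in% names(dt)]
  if (length(absent)) {
    stop("mapped column(s) not present in header of ", path, ": ",
         paste(sprintf("%s (field %s)", absent, names(absent)),
               collapse = ", "))
  }
  out <- data.frame(
    variant_id = as.character(dt[[column_map[["variant_id"]]]]),
    effect_allele = toupper(as.character(dt[[column_map[["effect_allele"]]]])),
    other_allele = toupper(as.character(dt[[column_map[["other_allele"]]]])),
    beta = as.numeric(dt[[column_map[["beta"]]]]),
    se = as.numeric(dt[[column_map[["se"]]]]),
    stringsAsFactors = FALSE
  )
  for (opt in c("eaf", "info", "chrom", "pos")) {
    if (opt %in% names(column_map)) {
      out[[opt]] <- if (opt == "chrom") {
        as.character(dt[[column_map[[opt]]]])
      } else {
        as.numeric(dt[[column_map[[opt]]]])
      }
    }
  }
  bad <- !is.finite(out$beta) | !is.finite(out$se) | out$se <= 0
  n_dropped <- sum(bad)
  out <- out[!bad, , drop = FALSE]
  dup <- duplicated(out$variant_id)
  if (any(dup)) {
    warning(sum(dup), " duplicated variant id(s) in ", path,
            "; keeping first occurrence")
    n_dropped <- n_dropped + sum(dup)
    out <- out[!dup, , drop = FALSE]
  }
  if (!quiet && n_dropped > 0) {
    message("read_sumstats: dropped ", n_dropped, " of ", nrow(dt),
            " rows (missing/non-positive se, non-finite beta, duplicates)")
  }
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

.palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonise incidence and prognosis summary statistics
#'
#' Intersects two summary-statistic tables on variant id and aligns the
#' prognosis effects to the incidence effect allele. If the prognosis
#' alleles are swapped relative to incidence, the prognosis effect is
#' negated and its allele frequency replaced by one minus the frequency.
#' Variants whose allele pairs do not match even after swapping are
#' dropped, as are palindromic (A/T, C/G) variants when
#' `drop_palindromic` is `TRUE`, because their strand cannot be resolved
#' without reliable frequency information.
#'
#' @param incidence,prognosis Data frames as returned by
#'   [read_sumstats()]; the incidence scan carries the effects on disease
#'   occurrence, the prognosis scan the effects on the subsequent outcome
#'   conditional on disease.
#' @param drop_palindromic Drop palindromic variants (default `TRUE`).
#' @param quiet Suppress the message reporting dropped variants.
#'
#' @return A data frame of harmonised pairs with columns `variant_id`,
#'   `effect_allele`, `other_allele`, `beta_gx`, `se_gx`,
#'   `beta_gy_prime`, `se_gy`, `eaf`, `info_x`, `info_y`, `pruned`
#'   (initialised to `FALSE`; see [set_pruned()]).
#' @export
harmonize <- function(incidence, prognosis, drop_palindromic = TRUE,
                      quiet = FALSE) {
  ix <- match(prognosis$variant_id, incidence$variant_id)
  keep <- !is.na(ix)
  if (!any(keep)) {
    stop("no variants shared between incidence and prognosis tables")
  }
  prog <- prognosis[keep, , drop = FALSE]
  inc <- incidence[ix[keep], , drop = FALSE]

  same <- prog$effect_allele == inc$effect_allele &
    prog$other_allele == inc$other_allele
  swapped <- prog$effect_allele == inc$other_allele &
    prog$other_allele == inc$effect_allele
  mismatch <- !(same | swapped)

  beta_gy <- ifelse(swapped, -prog$beta, prog$beta)
  palin <- .palindromic(inc$effect_allele, inc$other_allele)
  drop <- mismatch | (drop_palindromic & palin)

  n_mismatch <- sum(mismatch)
  n_palin <- sum(drop_palindromic & palin & !mismatch)
  if (!quiet && (n_mismatch > 0 || n_palin > 0)) {
    message("harmonize: dropped ", n_mismatch, " allele-mismatched and ",
            n_palin, " palindromic variant(s)")
  }

  pairs <- data.frame(
    variant_id = inc$variant_id,
    effect_allele = inc$effect_allele,
    other_allele = inc$other_allele,
    beta_gx = inc$beta,
    se_gx = inc$se,
    beta_gy_prime = beta_gy,
    se_gy = prog$se,
    eaf = if ("eaf" %in% names(inc)) inc$eaf else NA_real_,
    info_x = if ("info" %in% names(inc)) inc$info else NA_real_,
    info_y = if ("info" %in% names(prog)) prog$info else NA_real_,
    chrom = if ("chrom" %in% names(inc)) inc$chrom else NA_character_,
    pos = if ("pos" %in% names(inc)) inc$pos else NA_real_,
    pruned = FALSE,
    stringsAsFactors = FALSE
  )
  pairs <- pairs[!drop, , drop = FALSE]
  if (nrow(pairs) == 0L) {
    stop("no harmonisable variants shared between the two tables")
  }
  rownames(pairs) <- NULL
  attr(pairs, "n_mismatch") <- n_mismatch
  attr(pairs, "n_palindromic") <- n_palin
  pairs
}

#' Filter harmonised pairs on imputation quality and allele frequency
#'
#' Retains pairs whose imputation info scores in both scans are at least
#' `min_info` and whose effect-allele frequency lies in
#' `[min_eaf, 1 - min_eaf]`. A missing info score or frequency passes the
#' corresponding filter only when its threshold is 0, so low-quality
#' variants are not admitted silently.
#'
#' @param pairs Data frame from [harmonize()].
#' @param min_info Minimum imputation info/R-squared in both scans,
#'   in \[0, 1\].
#' @param min_eaf Minimum effect-allele frequency (and maximum
#'   `1 - min_eaf`), in \[0, 0.5\].
#'
#' @return The retained pairs, with attribute `n_filtered` giving the
#'   number removed.
#' @export
filter_pairs <- function(pairs, min_info = 0, min_eaf = 0) {
  stopifnot(min_info >= 0, min_info <= 1, min_eaf >= 0, min_eaf <= 0.5)
  ok_info <- if (min_info == 0) {
    rep(TRUE, nrow(pairs))
  } else {
    !is.na(pairs$info_x) & !is.na(pairs$info_y) &
      pairs$info_x >= min_info & pairs$info_y >= min_info
  }
  ok_eaf <- if (min_eaf == 0) {
    rep(TRUE, nrow(pairs))
  } else {
    !is.na(pairs$eaf) & pairs$eaf >= min_eaf & pairs$eaf <= 1 - min_eaf
  }
  keep <- ok_info & ok_eaf
  if (!any(keep)) {
    warning("filter_pairs: no pairs pass the filters")
  }
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_filtered") <- sum(!keep)
  out
}

#' Flag the variants used in the slope regression
#'
#' Sets the `pruned` flag of the harmonised pairs from a vector of
#' variant ids, typically the output of [greedy_ld_prune()] or an
#' externally produced LD-pruned list, optionally removing variants in
#' excluded regions (for example major susceptibility genes whose effects
#' have been conditioned on).
#'
#' @param pairs Data frame from [harmonize()].
#' @param ids Character vector of variant ids forming the slope-estimation
#'   subset.
#' @param exclude Optional character vector of variant ids to withhold
#'   from the subset even if present in `ids`.
#'
#' @return `pairs` with its `pruned` column updated.
#' @export
set_pruned <- function(pairs, ids, exclude = NULL) {
  flag <- pairs$variant_id %in% ids
  if (!is.null(exclude)) {
    flag <- flag & !(pairs$variant_id %in% exclude)
  }
  pairs$pruned <- flag
  pairs
}

#' Write adjusted association results
#'
#' Writes a tab-delimited table of bias-corrected prognosis effects with a
#' fixed column order. Numeric values are written with 17 significant
#' digits so that reading the file back reproduces them exactly,
#' including p-values near the double-precision underflow limit.
#'
#' @param records Data frame as returned by [adjust_effects()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_adjusted <- function(records, path) {
  cols <- c("variant_id", "beta_gx", "se_gx", "beta_gy_prime", "se_gy",
            "beta_gy_adj", "se_adj", "z", "p")
  out <- records[, cols, drop = FALSE]
  for (cl in cols[-1]) {
    out[[cl]] <- sprintf("%.17g", out[[cl]])
  }
  ok <- tryCatch({
    utils::write.table(out, file = path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write adjusted results to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read a plain-text list of variant ids
#'
#' One id per line; empty lines are ignored.
#'
#' @param path File path.
#' @return Character vector of ids.
#' @export
read_id_list <- function(path) {
  if (!file.exists(path)) stop("id list not found: ", path)
  ids <- readLines(path, warn = FALSE)
  ids <- trimws(ids)
  ids[nzchar(ids)]
}
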