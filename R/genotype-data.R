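#' Assemble a case-control genotype data frame
#'
#' The package represents a case-control genotype sample as an ordinary tibble
#' with one row per individual: a `sample_id` column, a `status` column coded
#' `1` for cases and `0` for controls, and one integer column per biallelic
#' variant holding minor-allele counts in `{0, 1, 2}` (or `NA` for missing
#' calls). All modelling functions take this tibble as their first argument,
#' so analyses chain naturally with the pipe.
#'
#' @param genotypes Matrix or data frame of minor-allele counts
#'   (individuals x variants), values in `{0, 1, 2, NA}`.
#' @param status Case/control status per individual: `1`/`0`, a logical, or a
#'   character/factor with levels `"case"`/`"control"`.
#' @param sample_id Optional character vector of sample identifiers; defaults
#'   to the rownames of `genotypes` or `S1, S2, ...`.
#' @param variant_ids Optional character vector of variant identifiers;
#'   defaults to the column names of `genotypes` or `V1, V2, ...`.
#' @param missing How missing genotypes are handled downstream: `"impute0"`
#'   (default) replaces `NA` with 0 (major-allele homozygote), `"category"`
#'   keeps `NA` as its own genotype level.
#'
#' @return A tibble with columns `sample_id`, `status`, then one column per
#'   variant.
#' @examples
#' g <- matrix(c(0, 1, 2, 0, 0, 1), nrow = 3)
#' genotype_data(g, status = c(1, 1, 0))
#' @export
genotype_data <- function(genotypes, status, sample_id = NULL,
                          variant_ids = NULL,
                          missing = c("impute0", "category")) {
  missing <- match.arg(missing)
  genotypes <- as.matrix(genotypes)
  if (is.null(variant_ids)) {
    variant_ids <- colnames(genotypes)
    if (is.null(variant_ids)) variant_ids <- paste0("V", seq_len(ncol(genotypes)))
  }
  if (is.null(sample_id)) {
    sample_id <- rownames(genotypes)
    if (is.null(sample_id)) sample_id <- paste0("S", seq_len(nrow(genotypes)))
  }
  status <- coerce_status(status)
  if (length(status) != nrow(genotypes)) {
    abort_invalid("`status` must have one entry per row of `genotypes`.")
  }
  storage.mode(genotypes) <- "integer"
  if (missing == "impute0") genotypes[is.na(genotypes)] <- 0L
  colnames(genotypes) <- variant_ids
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = as.character(sample_id), status = status),
    tibble::as_tibble(genotypes)
  )
  validate_genotype_data(out)
}

coerce_status <- function(status) {
  if (is.factor(status)) status <- as.character(status)
  if (is.character(status)) {
    low <- tolower(status)
    bad <- !low %in% c("case", "control", "0", "1")
    if (any(bad)) {
      abort_invalid(c("`status` has values other than case/control or 0/1.",
                      i = paste("Offending values:",
                                paste(unique(status[bad]), collapse = ", "))))
    }
    return(as.integer(low %in% c("case", "1")))
  }
  if (is.logical(status)) return(as.integer(status))
  s <- as.integer(status)
  if (any(is.na(s)) || !all(s %in% c(0L, 1L))) {
    abort_invalid("`status` must be coded 1 (case) / 0 (control) with no NA.")
  }
  s
}

#' Validate a case-control genotype data frame
#'
#' Checks the container contract: `sample_id` and `status` columns present,
#' status coded 0/1 with at least one case and one control, genotype columns
#' integer-valued in `{0, 1, 2, NA}`.
#'
#' @param data A genotype tibble as produced by [genotype_data()].
#' @return `data`, invisibly unchanged, as a tibble.
#' @export
validate_genotype_data <- function(data) {
  if (!is.data.frame(data)) abort_invalid("`data` must be a data frame.")
  if (!all(c("sample_id", "status") %in% names(data))) {
    abort_schema("`data` must have `sample_id` and `status` columns.")
  }
  data <- tibble::as_tibble(data)
  vcols <- variant_cols(data)
  if (length(vcols) == 0L) abort_invalid("`data` has no variant columns.")
  y <- data$status
  if (!all(y %in% c(0L, 1L))) {
    abort_invalid("`status` must be coded 1 (case) / 0 (control).")
  }
  g <- as.matrix(data[vcols])
  ok <- is.na(g) | g == 0 | g == 1 | g == 2
  if (!all(ok)) {
    abort_invalid("Genotype values must be minor-allele counts in {0, 1, 2} or NA.")
  }
  data
}

variant_cols <- function(data) setdiff(names(data), c("sample_id", "status"))

# Internal: split a genotype tibble into matrix parts used by the kernels.
gd_parts <- function(data) {
  data <- validate_genotype_data(data)
  vc <- variant_cols(data)
  g <- as.matrix(data[vc])
  storage.mode(g) <- "integer"
  list(G = g, y = as.integer(data$status), ids = data$sample_id,
       variants = vc)
}

# Internal: resolve loci given as variant IDs or positions into column indices
# of the variant matrix (positions are 1-based over variant columns only).
resolve_loci <- function(loci, variants, what = "loci") {
  if (length(loci) == 0L) abort_invalid(sprintf("`%s` must be non-empty.", what))
  if (is.character(loci)) {
    idx <- match(loci, variants)
    if (anyNA(idx)) {
      abort_schema(c(sprintf("Unknown variant IDs in `%s`.", what),
                     i = paste("Missing:",
                               paste(loci[is.na(idx)], collapse = ", "))))
    }
    return(idx)
  }
  idx <- as.integer(loci)
  if (anyNA(idx) || any(idx < 1L) || any(idx > length(variants))) {
    abort_invalid(sprintf("`%s` indices must lie in 1..%d.", what,
                          length(variants)))
  }
  idx
}

#' Per-variant summary: minor allele frequency and carrier counts
#'
#' MAF is estimated on the pooled sample (cases and controls together) as half
#' the mean minor-allele count, folded into `[0, 0.5]`. Missing genotypes are
#' dropped from the estimate.
#'
#' @param data A genotype tibble (see [genotype_data()]).
#' @param maf_threshold Variants with MAF strictly below this are flagged rare.
#' @return A tibble with one row per variant: `variant_id`, `maf`, `carriers`
#'   (individuals with >= 1 minor allele), `rare`.
#' @export
variant_info <- function(data, maf_threshold = 0.01) {
  p <- gd_parts(data)
  af <- colMeans(p$G, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  tibble::tibble(
    variant_id = p$variants,
    maf = unname(maf),
    carriers = unname(colSums(p$G >= 1L, na.rm = TRUE)),
    rare = unname(maf < maf_threshold)
  )
}

check_two_classes <- function(y) {
  if (sum(y == 1L) == 0L || sum(y == 0L) == 0L) {
    abort_degenerate("This operation needs at least one case and one control.")
  }
  invisible(y)
}

# error helpers -----------------------------------------------------------

abort_invalid <- function(msg) rlang::abort(msg, class = "crocr_invalid_argument")
abort_degenerate <- function(msg) rlang::abort(msg, class = "crocr_degenerate_data")
abort_schema <- function(msg) rlang::abort(msg, class = "crocr_schema_error")
abort_alignment <- function(msg) rlang::abort(msg, class = "crocr_alignment_error")
abort_unsupported <- function(msg) rlang::abort(msg, class = "crocr_unsupported_record")
abort_timeout <- function(msg) rlang::abort(msg, class = "crocr_timeout")
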