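#' Read a case-control genotype dataset from disk
#'
#' Genotypes come either from a delimited text file (`format = "tsv"`:
#' samples in rows, first column the sample ID, remaining columns one variant
#' each with minor-allele counts in `{0, 1, 2, NA}`) or from a VCF of
#' biallelic SNVs (`format = "vcf"`, GT field; requires the vcfR package).
#' The phenotype is a separate two-column tab-separated table
#' (`sample_id`, `status` with 1 = case, 0 = control). Samples are aligned
#' by ID in the phenotype file's order; the two sources must contain exactly
#' the same samples.
#'
#' For VCF input the minor allele is determined from the pooled sample
#' frequency, not assumed from REF/ALT: when ALT turns out to be the major
#' allele the counts are flipped and a warning names the variants.
#' Multiallelic sites are rejected with their coordinates.
#'
#' @param genotypes Path to the genotype file.
#' @param phenotype Path to the phenotype TSV.
#' @param format `"tsv"` or `"vcf"`.
#' @param missing Missing-genotype policy, see [genotype_data()].
#' @return A genotype tibble (see [genotype_data()]).
#' @export
read_genotypes <- function(genotypes, phenotype,
                           format = c("tsv", "vcf"),
                           missing = c("impute0", "category")) {
  format <- match.arg(format)
  missing <- match.arg(missing)
  ph <- read_phenotype(phenotype)
  gt <- if (format == "tsv") read_genotype_tsv(genotypes) else read_genotype_vcf(genotypes)
  only_ph <- setdiff(ph$sample_id, rownames(gt))
  only_gt <- setdiff(rownames(gt), ph$sample_id)
  if (length(only_ph) || length(only_gt)) {
    abort_alignment(c(
      "Samples differ between the genotype and phenotype sources.",
      if (length(only_ph)) rlang::set_names(
        paste("Only in phenotype:", paste(only_ph, collapse = ", ")), "x"),
      if (length(only_gt)) rlang::set_names(
        paste("Only in genotypes:", paste(only_gt, collapse = ", ")), "x")))
  }
  gt <- gt[ph$sample_id, , drop = FALSE]
  genotype_data(gt, status = ph$status, sample_id = ph$sample_id,
                missing = missing)
}

read_phenotype <- function(path) {
  ph <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (ncol(ph) != 2L) {
    abort_schema("Phenotype file must have exactly two columns: sample ID and status.")
  }
  names(ph) <- c("sample_id", "status")
  ok <- ph$status %in% c("0", "1")
  if (!all(ok)) {
    abort_schema(c("Phenotype status must be coded 1 (case) / 0 (control).",
                   x = paste("Offending values:",
                             paste(unique(ph$status[!ok]), collapse = ", "))))
  }
  if (anyDuplicated(ph$sample_id)) {
    abort_schema("Phenotype file has duplicated sample IDs.")
  }
  ph$status <- as.integer(ph$status)
  ph
}

read_genotype_tsv <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  if (ncol(tb) < 2L) abort_schema("Genotype TSV needs a sample column plus variants.")
  m <- as.matrix(tb[-1])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(tb[[1]])
  m
}

read_genotype_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort_invalid("Reading VCF requires the vcfR package.")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) {
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    abort_unsupported(c(
      "Multiallelic sites are not supported.",
      x = paste("Sites:", paste(sprintf("%s:%s", fix[multi, "CHROM"],
                                        fix[multi, "POS"]), collapse = ", "))))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    x <- sub(":.*", "", x)
    a <- strsplit(gsub("\\|", "/", x), "/", fixed = FALSE)
    vapply(a, function(al) {
      if (any(al == "." | is.na(al))) return(NA_integer_)
      sum(al == "1")
    }, integer(1))
  }
  m <- apply(gt, 2, count_alt)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = list(NULL, colnames(gt)))
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- sprintf("%s_%s", fix[noid, "CHROM"], fix[noid, "POS"])
  # orient to the minor allele from the pooled sample frequency
  af <- rowMeans(m, na.rm = TRUE) / 2
  flip <- !is.na(af) & af > 0.5
  if (any(flip)) {
    rlang::warn(paste("ALT is the major allele at:",
                      paste(ids[flip], collapse = ", "),
                      "- genotype counts flipped to the minor allele."))
    m[flip, ] <- 2L - m[flip, , drop = FALSE]
  }
  out <- t(m)
  colnames(out) <- ids
  out
}

#' Write a genotype dataset as TSV files
#'
#' Writes the genotype matrix (samples in rows, variants in columns, first
#' column `sample_id`) and the two-column phenotype table; together they
#' round-trip through [read_genotypes()].
#'
#' @param data A genotype tibble.
#' @param genotypes,phenotype Output paths.
#' @return `data`, invisibly.
#' @export
write_genotypes <- function(data, genotypes, phenotype) {
  data <- validate_genotype_data(data)
  readr::write_tsv(data[c("sample_id", variant_cols(data))], genotypes)
  readr::write_tsv(data[c("sample_id", "status")], phenotype)
  invisible(data)
}

# model serialization -----------------------------------------------------

MODEL_FORMAT_VERSION <- 1L

#' Serialize a fitted risk model to JSON
#'
#' The model document records the selected loci, the LR table (genotype
#' tuple, case/control counts, LR), the selection trace, the collapsing plan
#' (groups listed by variant ID so the model is portable across files;
#' omitted when the model has no collapsed groups), the fitting configuration
#' and optional input checksums. Writing is canonical and deterministic:
#' writing, reading back and writing again is byte-identical, and refitting
#' with the same data and seed serializes to the same bytes.
#'
#' @param fit A `croc_fit`.
#' @param path Output path; if `NULL` the JSON is returned as a string.
#' @param provenance Optional named list of input checksums recorded
#'   verbatim.
#' @return The JSON string, invisibly if written to `path`.
#' @export
write_model <- function(fit, path = NULL, provenance = NULL) {
  stopifnot(inherits(fit, "croc_fit"))
  plan <- fit$collapsing_plan
  has_plan <- !is.null(plan) && nrow(plan) > 0L
  config <- fit$config[c("folds", "seed", "pseudocount", "epsilon",
                         "max_model_size", "cv_mode", "unseen_lr", "lr_cap")]
  if (has_plan) {
    config$maf_threshold <- fit$config$maf_threshold
    config$coding <- fit$config$coding
    config$collapse_cv <- fit$config$collapse_cv
  }
  doc <- list(
    format_version = MODEL_FORMAT_VERSION,
    loci = as.list(fit$loci),
    n_case = fit$n_case,
    n_control = fit$n_control,
    lr_table = if (is.null(fit$lr_table)) NULL else list(
      entries = lapply(seq_len(nrow(fit$lr_table)), function(i) list(
        genotype = fit$lr_table$genotype[i],
        n_case = fit$lr_table$n_case[i],
        n_control = fit$lr_table$n_control[i],
        lr = fit$lr_table$lr[i]
      ))
    ),
    trace = list(
      steps = lapply(seq_len(nrow(fit$trace)), function(i) list(
        step = fit$trace$step[i],
        locus = fit$trace$locus[i],
        train_auc = fit$trace$train_auc[i],
        cv_auc = fit$trace$cv_auc[i]
      )),
      chosen_size = fit$chosen_size
    ),
    collapsing = if (has_plan) list(
      maf_threshold = attr(plan, "maf_threshold"),
      coding = attr(plan, "coding"),
      groups = lapply(seq_len(nrow(plan)), function(i) list(
        pseudo_id = plan$pseudo_id[i],
        variants = as.list(plan$variants[[i]]),
        auc = plan$auc[i]
      ))
    ) else NULL,
    config = config,
    provenance = provenance
  )
  doc <- doc[!vapply(doc, is.null, logical(1))]
  json <- json_encode(doc)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

# Canonical JSON writer for the model document. jsonlite's writer rounds
# doubles to 15 significant digits; the model contract requires that a
# written model reloads to bit-identical LR values (predictions from a
# reloaded model equal the original's exactly), so numbers are emitted with
# the shortest decimal representation that round-trips.
num_str <- function(x) {
  if (is.na(x)) return("null")
  if (is.integer(x)) return(sprintf("%d", x))
  for (d in c(15L, 16L, 17L)) {
    s <- sprintf("%.*g", d, x)
    if (as.numeric(s) == x) return(s)
  }
  sprintf("%.17g", x)
}

json_str <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  paste0("\"", x, "\"")
}

json_encode <- function(x, indent = 0) {
  pad <- strrep(" ", indent)
  pad2 <- strrep(" ", indent + 2)
  if (is.null(x)) return("null")
  if (is.list(x)) {
    nm <- names(x)
    if (is.null(nm)) {
      if (length(x) == 0L) return("[]")
      items <- vapply(x, json_encode, character(1), indent = indent + 2)
      return(paste0("[\n", paste0(pad2, items, collapse = ",\n"), "\n", pad, "]"))
    }
    if (length(x) == 0L) return("{}")
    items <- vapply(seq_along(x), function(i) {
      paste0(json_str(nm[i]), ": ", json_encode(x[[i]], indent + 2))
    }, character(1))
    return(paste0("{\n", paste0(pad2, items, collapse = ",\n"), "\n", pad, "}"))
  }
  if (length(x) != 1L) {
    items <- vapply(seq_along(x), function(i) json_encode(x[i]), character(1))
    return(paste0("[", paste(items, collapse = ", "), "]"))
  }
  if (is.character(x)) return(json_str(x))
  if (is.logical(x)) return(if (is.na(x)) "null" else if (x) "true" else "false")
  num_str(x)
}

#' Read a serialized risk model
#'
#' Reconstructs a `croc_fit` from the JSON written by [write_model()].
#' Predictions from the reloaded model are identical to the original's.
#'
#' @param path Path to a model JSON file (or a JSON string).
#' @return A `croc_fit`.
#' @export
read_model <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$format_version) ||
      doc$format_version != MODEL_FORMAT_VERSION) {
    abort_schema(sprintf("Unsupported model format version: %s.",
                         doc$format_version %||% "<missing>"))
  }
  config <- doc$config
  loci <- as.character(unlist(doc$loci))
  table <- NULL
  if (!is.null(doc$lr_table)) {
    e <- doc$lr_table$entries
    tb <- tibble::tibble(
      genotype = vapply(e, function(x) x$genotype, character(1)),
      n_case = vapply(e, function(x) as.integer(x$n_case), integer(1)),
      n_control = vapply(e, function(x) as.integer(x$n_control), integer(1))
    )
    tb$case_freq <- tb$n_case / doc$n_case
    tb$control_freq <- tb$n_control / doc$n_control
    tb$lr <- vapply(e, function(x) as.numeric(x$lr), numeric(1))
    table <- structure(tb, class = c("lr_table", class(tibble::tibble()))) |>
      set_lr_attrs(loci = loci, pseudocount = config$pseudocount,
                   lr_cap = config$lr_cap, unseen_lr = config$unseen_lr,
                   n_case = as.integer(doc$n_case),
                   n_control = as.integer(doc$n_control))
  }
  steps <- doc$trace$steps
  trace <- tibble::tibble(
    step = vapply(steps, function(x) as.integer(x$step), integer(1)),
    locus = vapply(steps, function(x) x$locus, character(1)),
    train_auc = vapply(steps, function(x) as.numeric(x$train_auc), numeric(1)),
    cv_auc = vapply(steps, function(x) as.numeric(x$cv_auc), numeric(1))
  )
  plan <- NULL
  method <- "froc"
  if (!is.null(doc$collapsing)) {
    method <- "croc"
    gr <- doc$collapsing$groups
    plan <- tibble::tibble(
      pseudo_id = vapply(gr, function(x) x$pseudo_id, character(1)),
      variants = lapply(gr, function(x) as.character(unlist(x$variants))),
      size = vapply(gr, function(x) length(x$variants), integer(1)),
      auc = vapply(gr, function(x) as.numeric(x$auc), numeric(1)),
      auc_path = lapply(gr, function(x) as.numeric(x$auc))
    )
    plan <- structure(plan,
                      class = c("collapsing_plan", class(tibble::tibble())),
                      maf_threshold = doc$collapsing$maf_threshold,
                      coding = doc$collapsing$coding)
    config$maf_threshold <- doc$collapsing$maf_threshold
    config$coding <- doc$collapsing$coding
  }
  structure(list(
    loci = loci,
    lr_table = table,
    trace = trace,
    chosen_size = as.integer(doc$trace$chosen_size),
    collapsing_plan = plan,
    config = c(list(method = method), config),
    n_case = as.integer(doc$n_case),
    n_control = as.integer(doc$n_control)
  ), class = "croc_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
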