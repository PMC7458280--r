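#' Construct and validate a case-control genotype table
#'
#' The package's universal input is a tibble with one row per subject: a
#' `sample` column of unique identifiers, a binary `status` column
#' (1 = case/athlete, 0 = control/sedentary), and one integer column per SNP
#' holding the minor (derived) allele count 0/1/2, `NA` for a failed call.
#'
#' @param x A data frame with columns `sample`, `status`, and one column per
#'   SNP containing values in `{0, 1, 2, NA}`.
#' @param allele_labels Optional named list, one entry per SNP, each a
#'   character pair `c(ancestral, derived)` (e.g. `c("R", "X")` for
#'   ACTN3 R577X). Retained as metadata and used to decode allele-pair
#'   strings on read.
#' @return A `geno_tbl`: a tibble carrying the validated data and the
#'   `allele_labels` attribute.
#' @examples
#' gt <- genotype_table(tibble::tibble(
#'   sample = c("S1", "S2", "S3"),
#'   status = c(1L, 0L, 0L),
#'   rs1 = c(0L, 1L, 2L),
#'   rs2 = c(1L, NA, 0L)
#' ))
#' snp_names(gt)
#' @export
genotype_table <- function(x, allele_labels = NULL) {
  x <- as_tibble(x)
  if (!all(c("sample", "status") %in% names(x))) {
    abort("genotype table needs 'sample' and 'status' columns")
  }
  snps <- setdiff(names(x), c("sample", "status"))
  if (length(snps) < 1) abort("genotype table has no SNP columns")
  if (anyDuplicated(x$sample)) abort("sample ids are not unique")
  if (anyDuplicated(snps)) abort("SNP names are not unique")
  x$status <- as.integer(x$status)
  if (!all(x$status %in% c(0L, 1L))) abort("status must be 0 (control) or 1 (case)")
  if (sum(x$status == 1L) < 1 || sum(x$status == 0L) < 1) {
    abort("need at least one case and one control")
  }
  for (s in snps) {
    g <- x[[s]]
    if (!all(is.na(g) | g %in% c(0, 1, 2))) {
      abort(paste0("SNP '", s, "' has genotype values outside {0, 1, 2, NA}"))
    }
    x[[s]] <- as.integer(g)
  }
  if (!is.null(allele_labels)) {
    bad <- setdiff(names(allele_labels), snps)
    if (length(bad)) abort(paste("allele labels for unknown SNPs:", paste(bad, collapse = ", ")))
  }
  structure(x, allele_labels = allele_labels, class = c("geno_tbl", class(x)))
}

#' @rdname genotype_table
#' @export
snp_names <- function(x) setdiff(names(x), c("sample", "status"))

#' @rdname genotype_table
#' @export
allele_labels <- function(x) attr(x, "allele_labels")

# keep the class + metadata through dplyr verbs used internally
#' @export
`[.geno_tbl` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("sample", "status") %in% names(out))) {
    attr(out, "allele_labels") <- attr(x, "allele_labels")
    class(out) <- c("geno_tbl", setdiff(class(out), "geno_tbl"))
  }
  out
}

decode_allele_pairs <- function(g, snp, labels) {
  g <- trimws(as.character(g))
  alleles <- unique(unlist(strsplit(g[!is.na(g) & g != ""], "")))
  real <- setdiff(alleles, c("?", "N", "-", "."))
  if (length(real) > 2) {
    abort(paste0("SNP '", snp, "' has more than 2 distinct alleles: ",
                 paste(sort(real), collapse = ", ")))
  }
  anc <- labels[1]; der <- labels[2]
  out <- dplyr::case_when(
    g == paste0(anc, anc) ~ 0L,
    g %in% c(paste0(anc, der), paste0(der, anc)) ~ 1L,
    g == paste0(der, der) ~ 2L,
    TRUE ~ NA_integer_
  )
  unparsed <- is.na(out) & !is.na(g)
  if (any(unparsed)) {
    warn(paste0("SNP '", snp, "': ", sum(unparsed),
                " genotype string(s) not decodable with labels (",
                anc, ",", der, "); set to missing"))
  }
  out
}

#' Read a genotype table from TSV
#'
#' Expects a UTF-8 tab-separated file with header
#' `sample<TAB>status<TAB><rs...>`. SNP genotypes may be integers 0/1/2
#' (minor-allele counts) or allele-pair strings such as `"RX"` decoded via
#' `allele_labels`; undecodable strings become missing with a warning.
#'
#' @param path Path to the TSV file.
#' @param allele_labels Named list of `c(ancestral, derived)` character pairs
#'   for SNP columns encoded as allele pairs.
#' @return A [genotype_table()].
#' @export
read_genotype_table <- function(path, allele_labels = NULL) {
  if (!file.exists(path)) abort(paste("file not found:", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!all(c("sample", "status") %in% names(raw))) {
    abort("malformed header: expected columns 'sample' and 'status'")
  }
  snps <- setdiff(names(raw), c("sample", "status"))
  for (s in snps) {
    g <- raw[[s]]
    if (all(is.na(g) | grepl("^[012]$", g))) {
      raw[[s]] <- as.integer(g)
    } else if (!is.null(allele_labels) && s %in% names(allele_labels)) {
      raw[[s]] <- decode_allele_pairs(g, s, allele_labels[[s]])
    } else {
      abort(paste0("SNP '", s, "' is not integer-coded and no allele labels were given"))
    }
  }
  raw$status <- as.integer(raw$status)
  genotype_table(raw, allele_labels = allele_labels)
}

#' Write a genotype table to TSV
#'
#' Inverse of [read_genotype_table()]: integer minor-allele counts, missing
#' written as empty fields. Reading the file back reproduces genotypes and
#' phenotypes exactly.
#'
#' @param gm A [genotype_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(gm, path) {
  readr::write_tsv(as_tibble(gm), path, na = "", progress = FALSE)
  invisible(path)
}

#' Read bi-allelic SNPs from a VCF into a genotype table
#'
#' Keeps bi-allelic SNP records only; multi-allelic records are skipped and
#' counted. GT fields are mapped `0/0 -> 0`, `0/1` or `1/0 -> 1`,
#' `1/1 -> 2`, `./. -> NA` (phased separators accepted).
#'
#' @param path Path to a VCF (v4.x) file.
#' @param sample_status Named integer vector mapping every VCF sample name to
#'   case (1) / control (0) status.
#' @return A [genotype_table()] with attribute `n_skipped`, the number of
#'   multi-allelic records dropped.
#' @export
read_vcf_biallelic <- function(path, sample_status) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  missing_status <- setdiff(samples, names(sample_status))
  if (length(missing_status)) {
    abort(paste("samples absent from status map:", paste(missing_status, collapse = ", ")))
  }
  biallelic <- !grepl(",", fix$ALT)
  n_skipped <- sum(!biallelic)
  if (n_skipped) inform(paste("skipped", n_skipped, "multi-allelic record(s)"))
  gt <- gt[biallelic, , drop = FALSE]
  ids <- fix$ID[biallelic]
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM[biallelic], ":", fix$POS[biallelic])[is.na(ids) | ids == "."]
  code_gt <- function(x) {
    x <- gsub("\\|", "/", x)
    dplyr::case_when(
      x == "0/0" ~ 0L,
      x %in% c("0/1", "1/0") ~ 1L,
      x == "1/1" ~ 2L,
      TRUE ~ NA_integer_
    )
  }
  mat <- apply(gt, 2, code_gt)
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = nrow(gt), dimnames = dimnames(gt))
  out <- tibble(sample = samples,
                status = as.integer(sample_status[samples]))
  for (i in seq_along(ids)) out[[ids[i]]] <- as.integer(mat[i, ])
  gm <- genotype_table(out)
  attr(gm, "n_skipped") <- n_skipped
  gm
}

#' Stratified hold-out split
#'
#' Splits subjects into training and test partitions, stratified by
#' case/control status. The total test size is `round(test_fraction * N)`,
#' apportioned across strata by largest remainder so each partition keeps the
#' overall case fraction within one subject per stratum. Deterministic given
#' `seed`.
#'
#' @param gm A [genotype_table()].
#' @param test_fraction Fraction of subjects held out; must be in (0, 0.5).
#' @param seed Integer seed for the within-stratum draw.
#' @return A `data_split` list with `train_indices`, `test_indices` (row
#'   indices into `gm`) and `seed`.
#' @export
holdout_split <- function(gm, test_fraction = 36 / 318, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 0.5) abort("test_fraction must be in (0, 0.5)")
  n <- nrow(gm)
  n_test <- round(test_fraction * n)
  strata <- split(seq_len(n), gm$status)
  if (any(lengths(strata) < 2)) abort("each status stratum needs at least 2 subjects")
  quota <- lengths(strata) * test_fraction
  base <- floor(quota)
  rem <- quota - base
  short <- n_test - sum(base)
  take <- base
  if (short > 0) {
    bump <- order(rem, decreasing = TRUE)[seq_len(short)]
    take[bump] <- take[bump] + 1
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  test_idx <- sort(unlist(Map(function(idx, k) sample(idx, k), strata, take), use.names = FALSE))
  structure(
    list(train_indices = setdiff(seq_len(n), test_idx),
         test_indices = test_idx,
         seed = as.integer(seed)),
    class = "data_split"
  )
}

# Save/restore global RNG state so seeded helpers don't perturb user RNG.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
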