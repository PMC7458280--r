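#' Case/control genotype contingency table for one SNP
#'
#' Tabulates non-missing subjects into a 2 (case/control) x 3 (minor-allele
#' count 0/1/2) table.
#'
#' @param gm A [genotype_table()].
#' @param snp SNP column name.
#' @param group One of `"all"`, `"case"`, `"control"`; restricts the subjects
#'   tabulated (the returned tibble always has both rows, one may be all
#'   zero when a single group is requested).
#' @return A tibble with columns `group`, `n0`, `n1`, `n2`; attribute
#'   `n_dropped` counts subjects excluded for a missing call.
#' @export
genotype_counts <- function(gm, snp, group = c("all", "case", "control")) {
  group <- match.arg(group)
  if (!snp %in% snp_names(gm)) abort(paste0("unknown SNP '", snp, "'"))
  g <- gm[[snp]]
  status <- gm$status
  keep <- !is.na(g)
  if (group == "case") keep <- keep & status == 1L
  if (group == "control") keep <- keep & status == 0L
  if (!any(keep)) abort(paste0("no non-missing genotypes for '", snp, "' in group '", group, "'"))
  tab <- table(factor(status[keep], levels = c(1, 0)),
               factor(g[keep], levels = c(0, 1, 2)))
  out <- tibble(
    group = c("case", "control"),
    n0 = as.integer(tab[, "0"]),
    n1 = as.integer(tab[, "1"]),
    n2 = as.integer(tab[, "2"])
  )
  attr(out, "n_dropped") <- sum(is.na(g))
  attr(out, "snp") <- snp
  out
}

#' Minor allele frequency from genotype counts
#'
#' @param counts Numeric vector `(n0, n1, n2)` of genotype counts by
#'   minor-allele dose.
#' @return A list with `maf` (in `[0, 0.5]`) and `flipped` (`TRUE` when the
#'   nominal minor allele had frequency > 0.5 and orientation was flipped).
#' @examples
#' minor_allele_frequency(c(100, 100, 45))$maf # 190/490
#' @export
minor_allele_frequency <- function(counts) {
  stopifnot(length(counts) == 3, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) abort("no subjects: cannot compute MAF")
  f <- (2 * counts[3] + counts[2]) / (2 * n)
  flipped <- FALSE
  if (f > 0.5) {
    f <- 1 - f
    flipped <- TRUE
  }
  list(maf = unname(f), flipped = flipped)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson chi-square on observed genotype counts against expected
#' Hardy-Weinberg proportions (p^2, 2pq, q^2) at the sample allele frequency,
#' 1 degree of freedom, no continuity correction. The equilibrium call uses
#' the fixed threshold chi^2 <= 6.635 (the 0.01 quantile at df 1).
#'
#' @param counts Genotype counts `(n0, n1, n2)`.
#' @param threshold Rejection threshold for the chi-square statistic.
#' @return An `hwe_result` list: `chi2`, `df`, `threshold`, `in_equilibrium`,
#'   `expected_counts` (sums to N exactly), `monomorphic`, `p_minor`.
#' @examples
#' hwe_test(c(25, 50, 25))$chi2 # 0: exact HWE proportions
#' hwe_test(c(50, 0, 50))$in_equilibrium # FALSE: complete heterozygote deficit
#' @export
hwe_test <- function(counts, threshold = 6.635) {
  stopifnot(length(counts) == 3, all(counts >= 0))
  n <- sum(counts)
  if (n < 1) abort("empty genotype counts")
  q <- (2 * counts[3] + counts[2]) / (2 * n) # minor allele
  p <- 1 - q
  expected <- n * c(p^2, 2 * p * q, q^2)
  monomorphic <- q == 0 || q == 1
  if (monomorphic) {
    chi2 <- 0
  } else {
    chi2 <- sum((counts - expected)^2 / expected)
  }
  structure(
    list(chi2 = unname(chi2), df = 1L, threshold = threshold,
         in_equilibrium = unname(chi2 <= threshold),
         expected_counts = unname(expected),
         monomorphic = monomorphic, p_minor = unname(q)),
    class = "hwe_result"
  )
}

#' Per-SNP quality-control report
#'
#' One row per SNP x group (`all`, `case`, `control`) with genotype counts,
#' minor allele frequency, and the Hardy-Weinberg chi-square. HWE is tested
#' on the combined sample by default; set `hwe_group = "control"` for the
#' control-only convention.
#'
#' @param gm A [genotype_table()].
#' @param hwe_group Group whose counts feed the HWE test, `"all"` or
#'   `"control"`.
#' @return A tibble with columns `snp`, `group`, `n0`, `n1`, `n2`, `maf`,
#'   `maf_flipped`, `hwe_chi2`, `hwe_pass` (HWE columns filled on the
#'   `hwe_group` rows, `NA` elsewhere).
#' @export
qc_report <- function(gm, hwe_group = c("all", "control")) {
  hwe_group <- match.arg(hwe_group)
  purrr::map_dfr(snp_names(gm), function(s) {
    ct <- genotype_counts(gm, s)
    rows <- tibble(
      snp = s,
      group = c("all", "case", "control"),
      n0 = c(sum(ct$n0), ct$n0),
      n1 = c(sum(ct$n1), ct$n1),
      n2 = c(sum(ct$n2), ct$n2)
    )
    maf <- purrr::map(seq_len(3), function(i) {
      cnt <- c(rows$n0[i], rows$n1[i], rows$n2[i])
      if (sum(cnt) == 0) list(maf = NA_real_, flipped = NA) else minor_allele_frequency(cnt)
    })
    rows$maf <- purrr::map_dbl(maf, "maf")
    rows$maf_flipped <- purrr::map_lgl(maf, ~ isTRUE(.x$flipped))
    rows$hwe_chi2 <- NA_real_
    rows$hwe_pass <- NA
    i <- which(rows$group == hwe_group)
    cnt <- c(rows$n0[i], rows$n1[i], rows$n2[i])
    h <- hwe_test(cnt)
    rows$hwe_chi2[i] <- h$chi2
    rows$hwe_pass[i] <- h$in_equilibrium
    rows
  })
}
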