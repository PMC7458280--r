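#' Genotype odds ratios OR1 and OR2 from a case/control table
#'
#' Per genotype g the odds are `odd_g = cases_g / controls_g`;
#' `OR1 = odd_Mm / odd_MM` (heterozygote vs major homozygote) and
#' `OR2 = odd_mm / odd_Mm` (minor homozygote vs heterozygote). Any zero cell
#' triggers the Haldane-Anscombe correction (+0.5 on every cell), flagged.
#'
#' @param counts_tbl A 2-row tibble as returned by [genotype_counts()]
#'   (columns `group`, `n0`, `n1`, `n2` with the case row first), or a
#'   2x3 matrix with rows case, control.
#' @return A list with `or1`, `or2`, `odds` (per-genotype case:control odds),
#'   and `zero_cell`.
#' @examples
#' tab <- tibble::tibble(group = c("case", "control"),
#'                       n0 = c(10, 20), n1 = c(10, 10), n2 = c(5, 10))
#' odds_ratios(tab) # or1 = 2, or2 = 0.5
#' @export
odds_ratios <- function(counts_tbl) {
  m <- as_or_matrix(counts_tbl)
  zero_cell <- any(m == 0)
  if (zero_cell) m <- m + 0.5
  odds <- m[1, ] / m[2, ]
  list(
    or1 = unname(odds[2] / odds[1]),
    or2 = unname(odds[3] / odds[2]),
    odds = unname(odds),
    zero_cell = zero_cell
  )
}

as_or_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(nrow(x) == 2, ncol(x) == 3)
    return(x)
  }
  stopifnot(is.data.frame(x), nrow(x) == 2)
  x <- x[order(match(x$group, c("case", "control"))), ]
  as.matrix(x[, c("n0", "n1", "n2")])
}

model_names <- c("dominant", "recessive", "additive", "multiplicative", "over-dominant")

#' Select the best-fitting inheritance model from OR1 and OR2
#'
#' Each classical single-SNP inheritance model pins the three genotype odds
#' to a one-parameter pattern; with `OR_mm = OR1 * OR2` the defining
#' constraints are: dominant `OR2 = 1`; recessive `OR1 = 1`; over-dominant
#' `OR_mm = 1`; multiplicative `OR_mm = OR1^2`; additive
#' `OR_mm = 2 * OR1 - 1`. Each model is scored by the squared deviation of
#' its constraint on the log-odds-ratio scale and the argmin is returned,
#' with all residuals exposed so near-ties can be audited. The additive
#' model is excluded (and flagged) when its predicted odds ratio
#' `2 * OR1 - 1` is non-positive.
#'
#' @param or1,or2 Genotype odds ratios as defined in [odds_ratios()].
#' @param snp Optional SNP name carried through to the result.
#' @return A `model_assignment` list: `snp`, `or1`, `or2`, `model`,
#'   `residuals` (named, NA for an excluded model), `additive_excluded`.
#' @examples
#' select_model(0.475, 0.949)$model # dominant
#' select_model(0.999, 1.309)$model # recessive
#' @export
select_model <- function(or1, or2, snp = NA_character_) {
  stopifnot(is.finite(or1), is.finite(or2), or1 > 0, or2 > 0)
  l1 <- log(or1)
  l2 <- log(or2)
  lmm <- l1 + l2
  res <- c(
    dominant = l2^2,
    recessive = l1^2,
    additive = NA_real_,
    multiplicative = (l2 - l1)^2,
    `over-dominant` = lmm^2
  )
  add_pred <- 2 * or1 - 1
  additive_excluded <- add_pred <= 0
  if (!additive_excluded) res["additive"] <- (lmm - log(add_pred))^2
  structure(
    list(snp = snp, or1 = or1, or2 = or2,
         model = names(which.min(res)),
         residuals = res,
         additive_excluded = additive_excluded),
    class = "model_assignment"
  )
}

#' Recode a SNP's genotypes under an inheritance model
#'
#' Collapses the three minor-allele-count categories into the model's risk
#' classes: dominant `{0} vs {1,2}`, recessive `{0,1} vs {2}`, over-dominant
#' `{1} vs {0,2}`; additive and multiplicative keep the three ordered
#' categories unchanged.
#'
#' @param genotypes Integer vector of minor-allele counts 0/1/2 (NA kept).
#' @param model One of `"dominant"`, `"recessive"`, `"additive"`,
#'   `"multiplicative"`, `"over-dominant"`.
#' @return Integer vector of recoded categories.
#' @export
recode_genotypes <- function(genotypes, model) {
  model <- match.arg(model, model_names)
  switch(model,
    dominant = as.integer(genotypes >= 1),
    recessive = as.integer(genotypes == 2),
    `over-dominant` = as.integer(genotypes == 1),
    as.integer(genotypes)
  )
}

#' Per-SNP inheritance-model report
#'
#' Runs [odds_ratios()] and [select_model()] on every SNP.
#'
#' @param gm A [genotype_table()].
#' @return A tibble with one row per SNP: `snp`, `or1`, `or2`, `model`, one
#'   `res_*` column per candidate model, `additive_excluded`, `zero_cell`.
#' @export
model_report <- function(gm) {
  purrr::map_dfr(snp_names(gm), function(s) {
    ors <- odds_ratios(genotype_counts(gm, s))
    ma <- select_model(ors$or1, ors$or2, snp = s)
    res <- as.list(ma$residuals)
    names(res) <- paste0("res_", gsub("-", "_", names(res)))
    tibble(snp = s, or1 = ors$or1, or2 = ors$or2, model = ma$model,
           !!!res, additive_excluded = ma$additive_excluded,
           zero_cell = ors$zero_cell)
  })
}
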