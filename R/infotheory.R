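#' Shannon entropy of a categorical attribute
#'
#' `H = -sum p_k log2 p_k` over non-empty categories, with `0 log 0 = 0`.
#'
#' @param x Vector of category labels (any atomic type; NA dropped).
#' @return Entropy in bits.
#' @examples
#' shannon_entropy(c(0, 1)) # 1 bit
#' shannon_entropy(rep("a", 10)) # 0
#' @export
shannon_entropy <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) abort("empty attribute")
  p <- table(x) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

joint_entropy <- function(a, b) {
  shannon_entropy(paste(a, b, sep = "\r"))
}

#' Mutual information between two attributes, in bits
#'
#' @param a,b Equal-length category vectors; pairwise-complete subjects only.
#' @return `I(A;B) = H(A) + H(B) - H(A,B)` in bits.
#' @export
mutual_information <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  shannon_entropy(a) + shannon_entropy(b) - joint_entropy(a, b)
}

#' Information gain of an attribute about the class, with G-square test
#'
#' The information gain is the mutual information `I(C;A) = H(C) - H(C|A)`
#' in bits; the likelihood-ratio statistic is `G^2 = 2 N ln(2) IG` with
#' `df = (|C|-1)(|A|-1)` and a chi-square p-value. Percent display follows
#' the bits x 100 convention; `percent_of_class_entropy` normalizes by
#' `H(C)` instead.
#'
#' @param class_attr Class labels (e.g. case/control status).
#' @param attr Genetic attribute (categories; NA pairs dropped).
#' @param percent_of_class_entropy If `TRUE`, `ig_percent` is
#'   `100 * ig_bits / H(C)`.
#' @return An `ig_result` list: `ig_bits`, `ig_percent`, `g2`, `df`,
#'   `p_value`, `n`.
#' @export
information_gain <- function(class_attr, attr, percent_of_class_entropy = FALSE) {
  stopifnot(length(class_attr) == length(attr))
  ok <- !is.na(class_attr) & !is.na(attr)
  c_ <- class_attr[ok]; a <- attr[ok]
  n <- length(c_)
  kc <- length(unique(c_)); ka <- length(unique(a))
  if (kc < 2 || ka < 2) {
    return(structure(list(ig_bits = 0, ig_percent = 0, g2 = 0, df = 0L,
                          p_value = 1, n = n), class = "ig_result"))
  }
  ig <- mutual_information(c_, a)
  ig <- max(ig, 0) # guard tiny negative float noise
  g2 <- 2 * n * log(2) * ig
  df <- (kc - 1L) * (ka - 1L)
  hc <- shannon_entropy(c_)
  structure(
    list(ig_bits = ig,
         ig_percent = if (percent_of_class_entropy) 100 * ig / hc else 100 * ig,
         g2 = g2, df = df,
         p_value = pchisq(g2, df, lower.tail = FALSE),
         n = n),
    class = "ig_result"
  )
}

product_attribute <- function(a, b) paste(a, b, sep = "\r")

#' Interaction information between two attributes in the context of a class
#'
#' `I(A;B;C) = IG(AxB;C) - IG(A;C) - IG(B;C)` where `AxB` is the Cartesian
#' product attribute over observed cells. Positive values indicate synergy
#' (the pair carries information about the class beyond its parts), negative
#' values redundancy.
#'
#' @param class_attr Class labels.
#' @param a,b Genetic attributes; subjects missing any of the three dropped.
#' @return An `interaction_result` list: `interaction_bits`,
#'   `interaction_percent` (bits x 100), `synergy`, `ig_a`, `ig_b`, `ig_ab`.
#' @export
interaction_information <- function(class_attr, a, b) {
  stopifnot(length(class_attr) == length(a), length(a) == length(b))
  ok <- !is.na(class_attr) & !is.na(a) & !is.na(b)
  c_ <- class_attr[ok]; a <- a[ok]; b <- b[ok]
  ig_a <- mutual_information(c_, a)
  ig_b <- mutual_information(c_, b)
  ig_ab <- mutual_information(c_, product_attribute(a, b))
  ii <- ig_ab - ig_a - ig_b
  structure(
    list(interaction_bits = ii, interaction_percent = 100 * ii,
         synergy = ii > 0, ig_a = ig_a, ig_b = ig_b, ig_ab = ig_ab),
    class = "interaction_result"
  )
}

#' Rajski distance between two attributes
#'
#' `d(A,B) = 1 - I(A;B)/H(A,B)`: 0 for informationally identical attributes,
#' 1 for independent ones. A constant pair (zero joint entropy) is defined
#' as distance 0.
#'
#' @param a,b Equal-length category vectors.
#' @return Distance in `[0, 1]`.
#' @export
rajski_distance <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  h_ab <- joint_entropy(a, b)
  if (h_ab == 0) return(0)
  d <- 1 - mutual_information(a, b) / h_ab
  min(max(d, 0), 1)
}

#' Per-SNP information-gain table
#'
#' @param gm A [genotype_table()].
#' @param recode_models Optional named character vector of inheritance models
#'   (see [recode_genotypes()]); when given, each SNP is recoded before the
#'   IG computation.
#' @inheritParams information_gain
#' @return A tibble: `snp`, `ig_bits`, `ig_percent`, `g2`, `df`, `p_value`, `n`.
#' @export
ig_report <- function(gm, recode_models = NULL, percent_of_class_entropy = FALSE) {
  purrr::map_dfr(snp_names(gm), function(s) {
    g <- gm[[s]]
    if (!is.null(recode_models) && s %in% names(recode_models)) {
      g <- recode_genotypes(g, recode_models[[s]])
    }
    r <- information_gain(gm$status, g, percent_of_class_entropy)
    tibble(snp = s, ig_bits = r$ig_bits, ig_percent = r$ig_percent,
           g2 = r$g2, df = r$df, p_value = r$p_value, n = r$n)
  })
}

#' Pairwise interaction-information table
#'
#' Computes `I(A;B;C)` for every SNP pair.
#'
#' @param gm A [genotype_table()].
#' @param recode_models Optional named model vector as in [ig_report()].
#' @return A tibble: `snp_a`, `snp_b`, `interaction_bits`,
#'   `interaction_percent`, `synergy`.
#' @export
interaction_report <- function(gm, recode_models = NULL) {
  snps <- snp_names(gm)
  if (length(snps) < 2) abort("need at least 2 SNPs")
  get_attr <- function(s) {
    g <- gm[[s]]
    if (!is.null(recode_models) && s %in% names(recode_models)) {
      g <- recode_genotypes(g, recode_models[[s]])
    }
    g
  }
  pairs <- combn(snps, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    r <- interaction_information(gm$status, get_attr(a), get_attr(b))
    tibble(snp_a = a, snp_b = b,
           interaction_bits = r$interaction_bits,
           interaction_percent = r$interaction_percent,
           synergy = r$synergy)
  })
}
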