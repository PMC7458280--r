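#' Simulation configuration for synthetic case-control genotype data
#'
#' Describes a population of independent bi-allelic loci in Hardy-Weinberg
#' equilibrium at given minor allele frequencies, with the case phenotype
#' driven by a two-locus penetrance surface on one designated pair (all
#' other loci act through a flat baseline penetrance, i.e. carry no signal).
#'
#' @param n_cases,n_controls Target subject counts per class.
#' @param snps A data frame with columns `name` and `maf` (each in
#'   `(0, 0.5]`).
#' @param epistatic_pair Optional list `list(snp_a =, snp_b =, penetrance =)`
#'   where `penetrance` is a 3x3 matrix of case probabilities indexed by
#'   minor-allele counts (row = snp_a 0/1/2, column = snp_b 0/1/2).
#' @param baseline_penetrance Case probability for subjects when no
#'   epistatic pair is configured (and the value multiplied into nothing
#'   else otherwise; loci outside the pair never affect status).
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_cases, n_controls, snps,
                              epistatic_pair = NULL,
                              baseline_penetrance = 0.23,
                              seed = 1L) {
  snps <- as_tibble(snps)
  stopifnot(all(c("name", "maf") %in% names(snps)),
            all(snps$maf > 0), all(snps$maf <= 0.5),
            n_cases >= 1, n_controls >= 1,
            baseline_penetrance > 0, baseline_penetrance < 1)
  if (anyDuplicated(snps$name)) abort("duplicate SNP names")
  if (!is.null(epistatic_pair)) {
    stopifnot(all(c("snp_a", "snp_b", "penetrance") %in% names(epistatic_pair)))
    if (!all(c(epistatic_pair$snp_a, epistatic_pair$snp_b) %in% snps$name)) {
      abort("epistatic pair names a SNP missing from the panel")
    }
    pen <- epistatic_pair$penetrance
    stopifnot(is.matrix(pen), dim(pen) == c(3, 3), all(pen >= 0), all(pen <= 1))
  }
  structure(
    list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         snps = snps, epistatic_pair = epistatic_pair,
         baseline_penetrance = baseline_penetrance, seed = as.integer(seed)),
    class = "sim_config"
  )
}

hwe_probs <- function(maf) c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)

#' XOR-parity two-locus penetrance surface
#'
#' A "pure epistasis" pattern: penetrance is `high` on cells where the
#' genotype parities of the two loci differ (one locus heterozygous, the
#' other homozygous) and `low` elsewhere. At MAF 0.5 the heterozygote
#' probability is exactly 1/2 at each locus, so both marginal penetrances
#' are flat at `(high + low)/2` — the signal is invisible to any
#' single-locus analysis.
#'
#' @param high,low Case probabilities for the two cell classes.
#' @return A 3x3 penetrance matrix.
#' @export
xor_penetrance <- function(high = 0.8, low = 0.2) {
  parity <- function(g) g %% 2
  outer(0:2, 0:2, function(a, b) ifelse(parity(a) != parity(b), high, low))
}

#' Generate a synthetic case-control genotype dataset
#'
#' Population genotypes are drawn per locus under Hardy-Weinberg
#' proportions at the configured MAF, loci independent. Case/control status
#' is assigned by rejection sampling: each drawn subject becomes a case
#' with probability equal to its penetrance (the epistatic-pair cell value,
#' or the baseline), and is kept only while its class quota is unfilled.
#' Deterministic given the config seed.
#'
#' @param config A [simulation_config()].
#' @param max_batches Safety cap on sampling rounds before declaring the
#'   requested counts unreachable.
#' @return A [genotype_table()] with `n_cases + n_controls` rows.
#' @export
generate_genotypes <- function(config, max_batches = 1000) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  snps <- config$snps
  k <- nrow(snps)
  need_cases <- config$n_cases
  need_controls <- config$n_controls
  batch <- max(4L * (need_cases + need_controls), 500L)
  kept <- list()
  for (b in seq_len(max_batches)) {
    g <- vapply(seq_len(k), function(j) {
      sample(0:2, batch, replace = TRUE, prob = hwe_probs(snps$maf[j]))
    }, integer(batch))
    colnames(g) <- snps$name
    if (is.null(config$epistatic_pair)) {
      pen <- rep(config$baseline_penetrance, batch)
    } else {
      ep <- config$epistatic_pair
      pen <- ep$penetrance[cbind(g[, ep$snp_a] + 1L, g[, ep$snp_b] + 1L)]
    }
    is_case <- runif(batch) < pen
    take_case <- which(is_case)[seq_len(min(sum(is_case), need_cases))]
    take_control <- which(!is_case)[seq_len(min(sum(!is_case), need_controls))]
    if (length(take_case)) {
      kept[[length(kept) + 1]] <- cbind(status = 1L, g[take_case, , drop = FALSE])
      need_cases <- need_cases - length(take_case)
    }
    if (length(take_control)) {
      kept[[length(kept) + 1]] <- cbind(status = 0L, g[take_control, , drop = FALSE])
      need_controls <- need_controls - length(take_control)
    }
    if (need_cases == 0 && need_controls == 0) break
  }
  if (need_cases > 0 || need_controls > 0) {
    abort("requested case/control counts unreachable under the configured penetrances")
  }
  m <- do.call(rbind, kept)
  out <- as_tibble(as.data.frame(m))
  out$sample <- sprintf("S%04d", seq_len(nrow(out)))
  out <- out[, c("sample", "status", snps$name)]
  genotype_table(out)
}

#' A packaged study-like simulation configuration
#'
#' Emulates the shape of a gymnast case-control candidate-SNP panel:
#' 73 cases and 245 controls (ratio 1:3.36), seven independent loci named
#' after the studied rs numbers with control MAFs between 0.165 and 0.5,
#' and an embedded epistatic pair on the loci standing in for rs1815739 and
#' rs362584 with an XOR-parity penetrance surface (near-zero marginal
#' effects).
#'
#' @param pen_high,pen_low Penetrance contrast of the embedded pair.
#' @param seed Integer seed.
#' @return A [simulation_config()].
#' @export
study_like_config <- function(pen_high = 0.4, pen_low = 0.1, seed = 1L) {
  snps <- tibble(
    name = c("rs1815739", "rs8192678", "rs4253778", "rs6265",
             "rs5443", "rs1076560", "rs362584"),
    maf = c(0.45, 0.35, 0.165, 0.20, 0.33, 0.17, 0.35)
  )
  simulation_config(
    n_cases = 73, n_controls = 245, snps = snps,
    epistatic_pair = list(snp_a = "rs1815739", snp_b = "rs362584",
                          penetrance = xor_penetrance(pen_high, pen_low)),
    baseline_penetrance = 73 / 318,
    seed = seed
  )
}

#' Closed-form joint distribution and interaction information of a config
#'
#' For the configured epistatic pair, computes the exact sample joint
#' distribution over (genotype A, genotype B, class) implied by
#' case-control sampling at the configured class sizes: within cases the
#' genotype probability is proportional to `P(g) * penetrance(g)`, within
#' controls to `P(g) * (1 - penetrance(g))`, and `P(class)` is fixed by the
#' quota. From it, the theoretical `I(A;B;C)` and the two marginal
#' penetrance vectors.
#'
#' @param config A [simulation_config()] with an epistatic pair.
#' @return A list: `joint` tibble (`ga`, `gb`, `class`, `prob`),
#'   `interaction_bits`, `marginal_penetrance_a`, `marginal_penetrance_b`.
#' @export
theoretical_pair_distribution <- function(config) {
  ep <- config$epistatic_pair
  if (is.null(ep)) abort("config has no epistatic pair")
  pa <- hwe_probs(config$snps$maf[config$snps$name == ep$snp_a])
  pb <- hwe_probs(config$snps$maf[config$snps$name == ep$snp_b])
  pg <- outer(pa, pb)
  pen <- ep$penetrance
  p_case <- config$n_cases / (config$n_cases + config$n_controls)
  w_case <- pg * pen / sum(pg * pen)
  w_ctrl <- pg * (1 - pen) / sum(pg * (1 - pen))
  joint <- bind_rows(
    tibble(ga = rep(0:2, 3), gb = rep(0:2, each = 3),
           class = 1L, prob = p_case * as.vector(w_case)),
    tibble(ga = rep(0:2, 3), gb = rep(0:2, each = 3),
           class = 0L, prob = (1 - p_case) * as.vector(w_ctrl))
  )
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  marg <- function(f) tapply(joint$prob, f, sum)
  h_c <- ent(marg(joint$class))
  h_a <- ent(marg(joint$ga)); h_b <- ent(marg(joint$gb))
  h_ac <- ent(marg(paste(joint$ga, joint$class)))
  h_bc <- ent(marg(paste(joint$gb, joint$class)))
  h_ab <- ent(marg(paste(joint$ga, joint$gb)))
  h_abc <- ent(joint$prob)
  ig_a <- h_a + h_c - h_ac
  ig_b <- h_b + h_c - h_bc
  ig_ab <- h_ab + h_c - h_abc
  list(
    joint = joint,
    interaction_bits = ig_ab - ig_a - ig_b,
    ig_a = ig_a, ig_b = ig_b,
    marginal_penetrance_a = as.vector((pg * pen) %*% rep(1, 3)) / pa,
    marginal_penetrance_b = as.vector(rep(1, 3) %*% (pg * pen)) / pb
  )
}
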