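# Fixtures are built in code; no data files.

# A small deterministic genotype table.
make_gm <- function(n_cases = 6, n_controls = 10, n_snps = 3, seed = 42) {
  withr::with_seed(seed, {
    n <- n_cases + n_controls
    df <- tibble::tibble(
      sample = sprintf("S%03d", seq_len(n)),
      status = c(rep(1L, n_cases), rep(0L, n_controls))
    )
    for (i in seq_len(n_snps)) {
      df[[paste0("rs", i)]] <- sample(0:2, n, replace = TRUE)
    }
    genotype_table(df)
  })
}

# Random 2 x k contingency-style attribute pair for property tests.
random_attrs <- function(n = 200, ka = 3, kb = 3, seed = 1) {
  withr::with_seed(seed, list(
    c = sample(0:1, n, replace = TRUE),
    a = sample(seq_len(ka) - 1, n, replace = TRUE),
    b = sample(seq_len(kb) - 1, n, replace = TRUE)
  ))
}

# Direct (oracle) entropy of a probability vector, base 2.
h2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Oracle mutual information from a raw joint count table.
mi_oracle <- function(x, y) {
  tab <- table(x, y)
  p <- tab / sum(tab)
  h2(rowSums(p)) + h2(colSums(p)) - h2(as.vector(p))
}

# Write a tiny VCF fixture; returns the path.
write_fixture_vcf <- function(path, n_multi = 2) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tP1\tP2\tP3"
  )
  gts <- list(c("0/0", "0/1", "1/1"), c("0/1", "1/0", "./."),
              c("1/1", "0/0", "0|1"), c("0/0", "0/0", "0/0"),
              c("0/1", "0/1", "1/1"), c("1/1", "./.", "0/0"),
              c("0/0", "1/1", "0/1"))
  recs <- vapply(seq_along(gts), function(i) {
    paste(c("1", 1000 + i, paste0("rsv", i), "A", "G", ".", "PASS", ".", "GT", gts[[i]]),
          collapse = "\t")
  }, character(1))
  multi <- vapply(seq_len(n_multi), function(i) {
    paste(c("1", 2000 + i, paste0("rsm", i), "A", "G,T", ".", "PASS", ".", "GT",
            c("0/1", "1/2", "0/0")), collapse = "\t")
  }, character(1))
  writeLines(c(header, recs, multi), path)
  path
}
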