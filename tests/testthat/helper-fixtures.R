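# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

# minimal hand-built screen: G genes x S shRNAs x L cell lines, optional
# driver gene depleted (logFC shift) in chosen mutant lines
toy_screen <- function(G = 6, S = 4, L = 8, seed = 1,
                       driver = NULL, driver_lines = NULL, shift = -2,
                       pools = c("poolA", "poolB"), residual_sd = 0.5) {
  set.seed(seed)
  genes <- sprintf("G%02d", seq_len(G))
  lines <- sprintf("CL%02d", seq_len(L))
  n <- G * S
  ids <- sprintf("s%03d", seq_len(n))
  gene_of <- rep(genes, each = S)
  seeds7 <- apply(matrix(sample(c("A", "C", "G", "T"), 7 * n, replace = TRUE),
                         nrow = n), 1, paste0, collapse = "")
  ge <- rnorm(G, 0, 0.5)
  lf <- matrix(rnorm(n * L, 0, residual_sd), n, L, dimnames = list(ids, lines)) +
    ge[rep(seq_len(G), each = S)]
  if (!is.null(driver))
    lf[gene_of == driver, driver_lines] <- lf[gene_of == driver, driver_lines] + shift
  ann <- data.frame(shrna_id = ids, gene = gene_of,
                    pool = rep_len(pools, n), seed = seeds7,
                    initial_abundance = 200, stringsAsFactors = FALSE)
  screen_dataset(ann, lf)
}

# stability table covering a screen's seeds
toy_stability <- function(screen, seed = 2, mean = -9, sd = 2) {
  set.seed(seed)
  u <- unique(screen$annotations$seed)
  seed_stability_table(u, rnorm(length(u), mean, sd))
}

# mutation table giving every gene >= n_mut mutant lines (round robin),
# with extra_gene/extra_lines overriding one gene's mutant set
toy_mutations <- function(screen, n_mut = 3, seed = 3,
                          driver = NULL, driver_lines = NULL) {
  set.seed(seed)
  genes <- unique(screen$annotations$gene)
  lines <- colnames(screen$logfc)
  g <- character(0); l <- character(0)
  off <- 0
  for (gn in genes) {
    if (!is.null(driver) && gn == driver) next
    pick <- lines[((off + seq_len(n_mut) - 1L) %% length(lines)) + 1L]
    off <- off + n_mut
    g <- c(g, rep(gn, n_mut)); l <- c(l, pick)
  }
  if (!is.null(driver)) {
    g <- c(g, rep(driver, length(driver_lines))); l <- c(l, driver_lines)
  }
  mutation_table(g, l, rep("Missense_Mutation", length(g)))
}

toy_cn <- function(screen) {
  genes <- unique(screen$annotations$gene)
  lines <- colnames(screen$logfc)
  copy_number_table(rep(genes, times = length(lines)),
                    rep(lines, each = length(genes)),
                    0L)
}

# independent brute-force integration of one cluster's marginal likelihood
# (trapezoid rule over the random intercept on a dense grid)
trapz_cluster_loglik <- function(r, mu0, theta, sigma) {
  u <- seq(-8 * sigma, 8 * sigma, length.out = 1e4)
  f <- vapply(u, function(ui)
    sum(dnbinom(r, mu = mu0 * exp(ui), size = theta, log = TRUE)) +
      dnorm(ui, 0, sigma, log = TRUE), numeric(1))
  m <- max(f)
  m + log(pracma::trapz(u, exp(f - m)))
}

# model-matched NB random-intercept data generator (independent of the
# package's likelihood code; used for calibration/recovery checks)
nb_glmm_data <- function(l = 20, ni = 10, b0 = log(500), b = -0.4,
                         theta = 5, sigma = 0.3) {
  x <- rep(c(0, 1), each = ceiling(l / 2))[seq_len(l)]
  u <- rnorm(l, 0, sigma)
  mu <- exp(b0 + b * x + u)
  r <- rnbinom(l * ni, mu = rep(mu, each = ni), size = theta)
  list(r = r, x = rep(x, each = ni),
       cell = rep(sprintf("c%03d", seq_len(l)), each = ni))
}
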