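# Shared fixtures and independent oracles, built in code at test time.

# small ad-hoc design
make_design <- function(I = 2, J = 2, K = 1, T = 2, guild = "insectivore") {
  survey_design(
    sites = sprintf("S%02d", seq_len(I)),
    strata = rep(c("inside", "out_0_400"), length.out = I),
    species = sprintf("SP%02d", seq_len(K)),
    guilds = rep(guild, K),
    years = seq_len(T) + 2013L,
    n_visits = J
  )
}

# brute-force marginal likelihood: enumerate every latent sequence
# z[1:T] in {0,1}^T per (site, species); independent of the package's
# forward recursion (direct probability arithmetic, no shared helpers)
enum_marginal <- function(y, params, x, design) {
  I <- dim(y)[1]; J <- dim(y)[2]; K <- dim(y)[3]; T <- dim(y)[4]
  C <- ncol(params$beta)
  total <- 0
  for (i in seq_len(I)) {
    for (k in seq_len(K)) {
      seqs <- as.matrix(expand.grid(rep(list(0:1), T)))
      lik <- 0
      for (r in seq_len(nrow(seqs))) {
        zseq <- seqs[r, ]
        pr <- 1
        for (t in seq_len(T)) {
          lp <- params$beta0[k]
          if (C > 0) lp <- lp + sum(params$beta[k, ] * x[i, , t])
          if (t > 1 && !is.null(params$phi)) {
            lp <- lp + params$phi[k] * zseq[t - 1]
          }
          psi <- 1 / (1 + exp(-lp))
          pr <- pr * if (zseq[t] == 1) psi else 1 - psi
          for (j in seq_len(J)) {
            yv <- y[i, j, k, t]
            if (is.na(yv)) next
            p <- 1 / (1 + exp(-params$alpha0[k, t])) * zseq[t]
            pr <- pr * if (yv == 1) p else 1 - p
          }
        }
        lik <- lik + pr
      }
      total <- total + log(lik)
    }
  }
  unname(total)
}

# random small model instance for oracle comparisons
random_instance <- function(I, J, K, T, with_na = TRUE) {
  design <- make_design(I, J, K, T)
  C <- sample(0:2, 1)
  params <- species_params(
    beta0 = rnorm(K, 0, 1),
    beta = matrix(rnorm(K * C), K, C),
    phi = rnorm(K, 0.5, 1),
    alpha0 = matrix(rnorm(K * T, -0.5, 1), K, T)
  )
  x <- array(rnorm(I * C * T), c(I, C, T))
  y <- array(rbinom(I * J * K * T, 1, 0.4), c(I, J, K, T))
  if (with_na && runif(1) < 0.7) {
    idx <- sample(length(y), ceiling(length(y) * 0.2))
    y[idx] <- NA_integer_
  }
  list(design = design, params = params, x = x, y = y)
}

# independent Kruskal-Wallis H (plain rank-sum formula with tie correction)
kw_h_oracle <- function(v, g) {
  r <- rank(v)
  n <- length(v)
  H <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / tabulate(as.integer(factor(g)))) - 3 * (n + 1)
  ties <- table(v)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr == 0) return(0)
  H / corr
}

# quick long-detections tibble from an array (for tests that build y directly)
detections_from_array <- function(y, design) {
  df <- expand.grid(i = seq_len(dim(y)[1]), j = seq_len(dim(y)[2]),
                    k = seq_len(dim(y)[3]), t = seq_len(dim(y)[4]))
  df$y <- y[as.matrix(df)]
  df <- df[!is.na(df$y), ]
  out <- tibble::tibble(
    site = design$sites$site[df$i], year = design$years[df$t],
    visit = df$j, species = design$species$species[df$k],
    y = as.integer(df$y)
  )
  out <- dplyr::arrange(out, site, year, visit, species)
  attr(out, "design") <- design
  out
}

# small covariate table with constant values (no covariate effect)
flat_covariates <- function(design) {
  tbl <- tidyr::crossing(site = design$sites$site, year = design$years)
  tbl$dist_solar <- seq_len(nrow(tbl)) # arbitrary non-constant
  tbl$orthoptera <- rev(seq_len(nrow(tbl)))
  tbl$grass <- seq_len(nrow(tbl)) * 0.5
  tbl$forb <- sin(seq_len(nrow(tbl)))
  as_covariates(tbl, design)
}
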