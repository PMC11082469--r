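#' Synthetic-series configuration
#'
#' Generative parameters for a synthetic yearly description series drawn
#' from the same model family the package fits. Defaults emulate the broad
#' features of a long botanical description record: a 1753-2020 span
#' (268 years), a baseline around 20 descriptions per year, strong
#' year-to-year persistence, heavy overdispersion, and a yearly author
#' process that allows author-free years.
#'
#' @param span Calendar span `c(start, end)`.
#' @param beta0 Intercept on the log scale (default `log(20)`).
#' @param beta_year Trend per centered/scaled year unit (default 0).
#' @param rho AR(1) coefficient in (-1, 1) (default 0.7).
#' @param sigma_ar AR innovation SD (>= 0; 0 disables the latent process).
#' @param shape Negative binomial shape (> 0; default 2).
#' @param author_process One of `list(type = "constant", k = )`,
#'   `list(type = "poisson", lambda = )` (default, lambda 8) or
#'   `list(type = "empirical", values = )` (sampled with replacement).
#' @param offset Include `log(author)` in the simulated log mean.
#' @param burst Optional two-state regime process adding episodic description
#'   pulses: `list(p_enter = , p_exit = , multiplier = )`; a quiet/burst
#'   Markov chain multiplies the mean by `multiplier` while in the burst
#'   state. `NULL` (default) disables it.
#' @param seed Integer RNG seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(span = c(1753, 2020), beta0 = log(20),
                             beta_year = 0, rho = 0.7, sigma_ar = 0.5,
                             shape = 2,
                             author_process = list(type = "poisson", lambda = 8),
                             offset = FALSE, burst = NULL, seed = 1) {
  if (abs(rho) >= 1) stop("`rho` must lie in (-1, 1)", call. = FALSE)
  if (sigma_ar < 0) stop("`sigma_ar` must be >= 0", call. = FALSE)
  if (shape <= 0) stop("`shape` must be > 0", call. = FALSE)
  if (!author_process$type %in% c("constant", "poisson", "empirical")) {
    stop("unknown author process type", call. = FALSE)
  }
  structure(list(span = as.integer(span), beta0 = beta0,
                 beta_year = beta_year, rho = rho, sigma_ar = sigma_ar,
                 shape = shape, author_process = author_process,
                 offset = isTRUE(offset), burst = burst,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Simulate a yearly description series with known parameters
#'
#' Draws a series from the package's generative model: a latent Gaussian
#' AR(1) process on the log mean (initialized from its stationary
#' distribution), an optional log author-count offset, and negative binomial
#' counts. The realized latent residuals and per-year means are returned so
#' recovery can be checked against the truth.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `series` (a [yearly_series()]) and `truth` (the config
#'   plus realized `r`, `mu`, `authors_raw`, and `x` — the centered/scaled
#'   year covariate).
#' @export
simulate_series <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  years <- cfg$span[1]:cfg$span[2]
  n <- length(years)
  x <- (years - mean(years)) / stats::sd(years)

  ap <- cfg$author_process
  a_raw <- switch(ap$type,
    constant = rep(as.integer(ap$k), n),
    poisson = stats::rpois(n, ap$lambda),
    empirical = sample(as.integer(ap$values), n, replace = TRUE))
  a <- ifelse(a_raw == 0, 0.1, a_raw)

  r <- numeric(n)
  if (cfg$sigma_ar > 0) {
    r[1] <- stats::rnorm(1, 0, cfg$sigma_ar / sqrt(1 - cfg$rho^2))
    for (t in 2:n) r[t] <- cfg$rho * r[t - 1] + stats::rnorm(1, 0, cfg$sigma_ar)
  }

  log_mu <- cfg$beta0 + cfg$beta_year * x + r +
    if (cfg$offset) log(a) else 0
  if (!is.null(cfg$burst)) {
    b <- cfg$burst
    state <- logical(n)
    for (t in 2:n) {
      state[t] <- if (state[t - 1]) stats::runif(1) > b$p_exit
                  else stats::runif(1) < b$p_enter
    }
    log_mu <- log_mu + log(b$multiplier) * state
  }
  mu <- exp(log_mu)
  counts <- stats::rnbinom(n, mu = mu, size = cfg$shape)
  # the recorded author series counts *describing* authors, so a year with
  # no descriptions records none, whatever the latent effort was; the latent
  # effort driving the mean is kept in the truth
  a_obs <- ifelse(counts == 0, 0.1, a)
  list(series = yearly_series(years, counts, a_obs),
       truth = c(unclass(cfg), list(r = r, mu = mu, authors_raw = a_raw,
                                    x = x)))
}

default_author_pool <- function() {
  # fictional abbreviations; no real botanist names
  sprintf("%s.", c("Abar", "Bevel", "Corvin", "Dren", "Elmis", "Farrow",
                   "Gorse", "Hollin", "Ives", "Jarrah", "Kestrel", "Lorn",
                   "Marl", "Nessel", "Orpin", "Pell", "Quance", "Rillet",
                   "Selden", "Tarn", "Umber", "Vessey", "Wrenfield", "Yarrow",
                   "Zelkov"))
}

#' Write a synthetic checklist whose tally reproduces a series
#'
#' Emits a WCVP-dialect delimited checklist (tab-separated, default column
#' names) with one accepted species row per description, constructed so that
#' [tally_series()] over the series span returns the input series exactly:
#' counts exactly, and author tallies exactly wherever the per-year author
#' target is an integer. If a year needs more unique authors than species,
#' the surplus authors are added as co-authors (`&`) on the first species;
#' a year with descriptions but an author target of 0 (the 0.1 floor) is
#' written with empty authorship strings, which tally back to 0.1.
#'
#' @param series A [yearly_series()] with integer author targets (0.1 years
#'   must have zero counts).
#' @param path Output file path.
#' @param author_pool Character vector of author abbreviations (fictional by
#'   default); must be at least as large as the largest yearly author
#'   target.
#' @param seed Integer seed (genus/epithet naming).
#' @return `path`, invisibly.
#' @export
simulate_checklist <- function(series, path,
                               author_pool = default_author_pool(),
                               seed = 1) {
  stopifnot(inherits(series, "yearly_series"))
  targets <- authors_raw(series)
  if (any(targets > 0 & series$counts == 0)) {
    stop("a year with authors but no species is not representable",
         call. = FALSE)
  }
  if (max(targets) > length(author_pool)) {
    stop("author pool too small for the largest yearly author target",
         call. = FALSE)
  }
  set.seed(seed)
  rows <- list()
  sp <- 0L
  for (i in seq_along(series$years)) {
    k <- series$counts[i]
    if (k == 0) next
    m <- targets[i]
    if (m == 0) {
      per_species <- rep(list(character(0)), k)
    } else {
      auth_year <- sample(author_pool, m)
      per_species <- as.list(auth_year[pmin(seq_len(k), m)])
      if (m > k) per_species[[1]] <- auth_year  # co-author the surplus
    }
    for (j in seq_len(k)) {
      sp <- sp + 1L
      rows[[sp]] <- data.frame(
        taxon_name = sprintf("Fictus species%04d", sp),
        taxon_status = "Accepted",
        taxon_authors = paste(per_species[[j]], collapse = " & "),
        first_published = sprintf("(%d)", series$years[i]))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(taxon_name = character(0), taxon_status = character(0),
               taxon_authors = character(0), first_published = character(0))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
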