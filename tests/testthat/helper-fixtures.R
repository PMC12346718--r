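# Fixture builders and independent oracles shared across the suite.

# One-substrate noiseless config: every noise source off, OM = dm = 1 g.
noiselessConfig <- function(A = 250, B = 10, C = 2, dom = 0.5,
                            times = c(seq(2, 24, by = 2), 30, 36, 48, 72,
                                      96, 120),
                            horizon = 120, replicates = 3L, runs = 1L,
                            blank_mean = 0, seed = 1L) {
  studyConfig(
    substrates = data.frame(label = "SUB", cut = NA_character_,
                            part = NA_character_, A = A, B = B, C = C,
                            dom = dom, om_frac = 1,
                            ac = 50, pr = 15, ib = 1.5, bu = 8, iv = 3,
                            va = 2, ph = 6.34, stringsAsFactors = FALSE),
    runs = runs, replicates = replicates, blanks_per_run = 1L,
    horizon_h = horizon, times_h = times,
    gas_sd_ml = 0, blank_mean_ml = blank_mean, blank_sd_ml = 0,
    vfa_cv = 0, dom_sd = 0, dm_g = 1, dm_sd_g = 0, seed = seed)
}

# Hand-built two-run study for blank-correction arithmetic.
handStudy <- function(gas, time_h, bottles) FermStudy(gas, time_h, bottles)

bottleRow <- function(id, substrate = "SUB", run = 1L, replicate = 1L,
                      om = 1, dm = 1, residue = 0.5) {
  blank <- substrate == "BLANK"
  data.frame(bottle_id = id, substrate = substrate, cut = NA_character_,
             part = NA_character_, run = run, replicate = replicate,
             incubated_dm_g = if (blank) 0 else dm,
             incubated_om_g = if (blank) 0 else om,
             residue_om_g = if (blank) 0 else residue,
             vfa_acetate = if (blank) NA_real_ else 50,
             vfa_propionate = if (blank) NA_real_ else 15,
             vfa_isobutyrate = if (blank) NA_real_ else 1.5,
             vfa_butyrate = if (blank) NA_real_ else 8,
             vfa_isovalerate = if (blank) NA_real_ else 3,
             vfa_valerate = if (blank) NA_real_ else 2,
             ph = if (blank) NA_real_ else 6.34, stringsAsFactors = FALSE)
}

# Independent oracle for the maximum fermentation rate: dense grid of
# central-difference derivatives of the model curve, no closed forms.
gridRateMax <- function(A, B, C, n_grid = 20000) {
  g <- function(t) A / (1 + (B / t)^C)
  tt <- seq(0.01 * B, 5 * B, length.out = n_grid)
  h <- 1e-5 * tt
  rate <- (g(tt + h) - g(tt - h)) / (2 * h)
  i <- which.max(rate)
  list(tmax = tt[i], rmax = rate[i], resolution = tt[2] - tt[1])
}

# Random valid VFA profiles for property tests.
randomProfiles <- function(n, seed = 1) {
  set.seed(seed)
  vfaProfile(acetate = runif(n, 0, 60), propionate = runif(n, 0, 25),
             isobutyrate = runif(n, 0, 3), butyrate = runif(n, 0, 12),
             isovalerate = runif(n, 0, 4), valerate = runif(n, 0, 3))
}

# Long table with k groups of n draws, optional per-group shifts.
mockOneWayTable <- function(shifts, n = 6, sd = 1, seed = 1,
                            response = "y") {
  set.seed(seed)
  k <- length(shifts)
  data.frame(bottle_id = sprintf("b%02d", seq_len(k * n)),
             substrate = rep(names(shifts) %||% paste0("G", seq_len(k)),
                             each = n),
             cut = NA_character_, part = NA_character_,
             run = 1L, replicate = rep(seq_len(n), k),
             response = response,
             value = rnorm(k * n, rep(shifts, each = n), sd),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
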