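#' Build a synthetic-study configuration
#'
#' Validates and assembles a [StudyConfig-class].  See that class for the
#' meaning of every field; [exp1Config()] / [exp2Config()] provide ready-made
#' designs.
#'
#' @param substrates substrate table (see [StudyConfig-class]).
#' @param runs,replicates,blanks_per_run design counts.
#' @param horizon_h incubation horizon (h).
#' @param times_h recording grid (h), strictly increasing, within
#'   `(0, horizon_h]`.
#' @param gas_sd_ml additive s.d. of a single gas reading (mL).
#' @param blank_mean_ml,blank_sd_ml mean and between-run s.d. of blank gas
#'   (mL).
#' @param vfa_cv multiplicative coefficient of variation of VFA end-points.
#' @param dom_sd per-bottle s.d. of the OM degradability fraction.
#' @param dm_g,dm_sd_g mean and s.d. of incubated dry matter (g).
#' @param seed integer master seed.
#' @return a validated [StudyConfig-class] object.
#' @export
studyConfig <- function(substrates, runs = 2L, replicates = 3L,
                        blanks_per_run = 2L, horizon_h = 120,
                        times_h = c(seq(2, 24, by = 2), 30, 36, 48, 72, 96, 120),
                        gas_sd_ml = 2, blank_mean_ml = 10, blank_sd_ml = 1,
                        vfa_cv = 0.05, dom_sd = 0.02,
                        dm_g = 1.0040, dm_sd_g = 0.0028, seed = 1L) {
  substrates <- as.data.frame(substrates, stringsAsFactors = FALSE)
  cfg <- try(new("StudyConfig", substrates = substrates,
                 runs = as.integer(runs), replicates = as.integer(replicates),
                 blanks_per_run = as.integer(blanks_per_run),
                 horizon_h = as.numeric(horizon_h),
                 times_h = as.numeric(times_h),
                 gas_sd_ml = as.numeric(gas_sd_ml),
                 blank_mean_ml = as.numeric(blank_mean_ml),
                 blank_sd_ml = as.numeric(blank_sd_ml),
                 vfa_cv = as.numeric(vfa_cv), dom_sd = as.numeric(dom_sd),
                 dm_g = as.numeric(dm_g), dm_sd_g = as.numeric(dm_sd_g),
                 seed = as.integer(seed)),
             silent = TRUE)
  if (inherits(cfg, "try-error"))
    stop("invalid study configuration: ",
         sub(".*invalid class [^:]*: *", "", attr(cfg, "condition")$message),
         call. = FALSE)
  cfg
}

# Deterministic per-unit RNG substream: every bottle (and every per-run blank
# constant) seeds its own stream from the master seed, so records are
# reproducible unit-by-unit and extending the design leaves earlier draws
# intact.  Strides keep all derived seeds well below 2^31 for small master
# seeds.
.unit_seed <- function(seed, unit) (seed + 1009L * unit) %% 2147483647L

.rnorm_seeded <- function(seed, n, mean = 0, sd = 1) {
  if (sd == 0) return(rep(mean, n))
  set.seed(seed)
  stats::rnorm(n, mean, sd)
}

# Noiseless sigmoidal curve, vectorized over t; 0 at t = 0 (model limit).
.groot <- function(A, B, C, t) ifelse(t > 0, A / (1 + (B / t)^C), 0)

#' Simulate a complete in vitro gas-production study
#'
#' Generates bottle-level records under a known ground truth: for a substrate
#' bottle the noiseless expected raw reading at time t is
#' `blank level + OM_incubated * A / (1 + (B/t)^C)`; residue OM is
#' `incubated OM * (1 - dOM)` before noise; VFA end-points are drawn
#' log-normally about their true means (exactly the means when `vfa_cv = 0`).
#' Blank bottles record the per-run blank level plus reading noise.  All
#' readings are truncated at 0.  The simulation is fully deterministic given
#' the config's seed.
#'
#' @param config a [StudyConfig-class] object.
#' @return a [FermStudy-class]; the config and the true parameter table are
#'   kept in `metadata(x)$config` and `metadata(x)$truth`.
#' @examples
#' study <- simulateStudy(exp1Config(seed = 42))
#' study
#' @export
simulateStudy <- function(config) {
  stopifnot(is(config, "StudyConfig"))
  validObject(config)
  s <- config@substrates
  tt <- config@times_h
  nt <- length(tt)

  bottles <- list(); gas <- list()
  unit <- 0L
  for (r in seq_len(config@runs)) {
    unit <- unit + 1L
    blank_level <- max(0, .rnorm_seeded(.unit_seed(config@seed, unit), 1,
                                        config@blank_mean_ml,
                                        config@blank_sd_ml))
    for (i in seq_len(nrow(s))) {
      for (k in seq_len(config@replicates)) {
        unit <- unit + 1L
        us <- .unit_seed(config@seed, unit)
        set.seed(us)
        dm <- max(1e-6, stats::rnorm(1, config@dm_g, config@dm_sd_g))
        om <- dm * s$om_frac[i]
        noise <- if (config@gas_sd_ml > 0)
          stats::rnorm(nt, 0, config@gas_sd_ml) else numeric(nt)
        g <- pmax(0, blank_level + om * .groot(s$A[i], s$B[i], s$C[i], tt) +
                       noise)
        dom_i <- min(1 - 1e-6, max(1e-6,
                 stats::rnorm(1, s$dom[i], config@dom_sd)))
        if (config@dom_sd == 0) dom_i <- s$dom[i]
        vmu <- as.numeric(s[i, c("ac", "pr", "ib", "bu", "iv", "va")])
        if (config@vfa_cv > 0) {
          sdlog <- sqrt(log(1 + config@vfa_cv^2))
          vfa <- vmu * exp(stats::rnorm(6, -sdlog^2 / 2, sdlog))
        } else vfa <- vmu
        ph <- stats::rnorm(1, s$ph[i], 0.02)
        bottles[[length(bottles) + 1L]] <- data.frame(
          bottle_id = sprintf("R%d_%s_%d", r, s$label[i], k),
          substrate = s$label[i], cut = s$cut[i], part = s$part[i],
          run = r, replicate = k,
          incubated_dm_g = dm, incubated_om_g = om,
          residue_om_g = om * (1 - dom_i),
          vfa_acetate = vfa[1], vfa_propionate = vfa[2],
          vfa_isobutyrate = vfa[3], vfa_butyrate = vfa[4],
          vfa_isovalerate = vfa[5], vfa_valerate = vfa[6],
          ph = ph, stringsAsFactors = FALSE)
        gas[[length(gas) + 1L]] <- g
      }
    }
    for (k in seq_len(config@blanks_per_run)) {
      unit <- unit + 1L
      us <- .unit_seed(config@seed, unit)
      noise <- if (config@gas_sd_ml > 0)
        .rnorm_seeded(us, nt, 0, config@gas_sd_ml) else numeric(nt)
      bottles[[length(bottles) + 1L]] <- data.frame(
        bottle_id = sprintf("R%d_BLANK_%d", r, k),
        substrate = "BLANK", cut = NA_character_, part = NA_character_,
        run = r, replicate = k,
        incubated_dm_g = 0, incubated_om_g = 0, residue_om_g = 0,
        vfa_acetate = NA_real_, vfa_propionate = NA_real_,
        vfa_isobutyrate = NA_real_, vfa_butyrate = NA_real_,
        vfa_isovalerate = NA_real_, vfa_valerate = NA_real_,
        ph = NA_real_, stringsAsFactors = FALSE)
      gas[[length(gas) + 1L]] <- pmax(0, blank_level + noise)
    }
  }
  bottles <- do.call(rbind, bottles)
  gasmat <- do.call(cbind, gas)
  FermStudy(gasmat, tt, bottles,
            metadata = list(config = config, truth = s))
}

#' Write / read a study as plain-text CSV
#'
#' `writeStudyCSV()` writes `bottles.csv` (one row per bottle) and
#' `gas_long.csv` (`bottle_id`, `time_h`, `gas_ml`) into `dir`;
#' `readStudyCSV()` rebuilds the [FermStudy-class] from them.  Values
#' round-trip at full double precision.
#'
#' @param study a [FermStudy-class] object.
#' @param dir directory (created if needed).
#' @return `writeStudyCSV()` the paths written, invisibly;
#'   `readStudyCSV()` a [FermStudy-class].
# Serialize doubles at 17 significant digits so CSV round-trips are exact.
.fmtFull <- function(df) {
  df[] <- lapply(df, function(col)
    if (is.double(col)) ifelse(is.na(col), NA_character_,
                               sprintf("%.17g", col)) else col)
  df
}

#' @export
writeStudyCSV <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bpath <- file.path(dir, "bottles.csv")
  gpath <- file.path(dir, "gas_long.csv")
  bd <- as.data.frame(colData(study))
  data.table::fwrite(.fmtFull(bd), bpath, na = "NA", quote = FALSE)
  g <- assay(study, "gas")
  long <- data.frame(
    bottle_id = rep(colnames(g), each = nrow(g)),
    time_h = rep(gasTimes(study), times = ncol(g)),
    gas_ml = as.vector(g), stringsAsFactors = FALSE)
  data.table::fwrite(.fmtFull(long), gpath, na = "NA", quote = FALSE)
  invisible(c(bottles = bpath, gas_long = gpath))
}

#' @param check validate the files with [validateInputs()] first.
#' @rdname writeStudyCSV
#' @export
readStudyCSV <- function(dir, check = TRUE) {
  bpath <- file.path(dir, "bottles.csv")
  gpath <- file.path(dir, "gas_long.csv")
  if (check) {
    v <- validateInputs(bottles = bpath, gas_long = gpath)
    if (nrow(v))
      stop("input validation failed:\n",
           paste(sprintf("  [%s] %s", v$file, v$problem), collapse = "\n"),
           call. = FALSE)
  }
  bd <- data.table::fread(bpath, data.table = FALSE, na.strings = "NA")
  long <- data.table::fread(gpath, data.table = FALSE, na.strings = "NA")
  for (f in intersect(c("cut", "part"), names(bd)))
    bd[[f]] <- as.character(bd[[f]])   # all-NA columns parse as logical
  tt <- sort(unique(long$time_h))
  gas <- matrix(NA_real_, length(tt), nrow(bd),
                dimnames = list(NULL, bd$bottle_id))
  idx <- cbind(match(long$time_h, tt), match(long$bottle_id, bd$bottle_id))
  gas[idx] <- long$gas_ml
  FermStudy(gas, tt, bd)
}

#' Round-trip a study configuration through JSON
#'
#' @param config a [StudyConfig-class] object.
#' @param path file path for the JSON representation.
#' @return `writeStudyConfig()` the path, invisibly; `readStudyConfig()` a
#'   validated [StudyConfig-class].
#' @export
writeStudyConfig <- function(config, path) {
  stopifnot(is(config, "StudyConfig"))
  x <- list(substrates = config@substrates,
            runs = config@runs, replicates = config@replicates,
            blanks_per_run = config@blanks_per_run,
            horizon_h = config@horizon_h, times_h = config@times_h,
            gas_sd_ml = config@gas_sd_ml,
            blank_mean_ml = config@blank_mean_ml,
            blank_sd_ml = config@blank_sd_ml,
            vfa_cv = config@vfa_cv, dom_sd = config@dom_sd,
            dm_g = config@dm_g, dm_sd_g = config@dm_sd_g, seed = config@seed)
  jsonlite::write_json(x, path, digits = I(17), auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname writeStudyConfig
#' @export
readStudyConfig <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$substrates <- as.data.frame(x$substrates, stringsAsFactors = FALSE)
  num <- setdiff(.substrate_cols, c("label", "cut", "part"))
  x$substrates[num] <- lapply(x$substrates[num], as.numeric)
  for (f in c("cut", "part"))   # all-NA factor columns: keep character
    if (f %in% names(x$substrates))
      x$substrates[[f]] <- as.character(x$substrates[[f]])
  for (f in c("horizon_h", "times_h", "gas_sd_ml", "blank_mean_ml",
              "blank_sd_ml", "vfa_cv", "dom_sd", "dm_g", "dm_sd_g"))
    x[[f]] <- as.numeric(x[[f]])
  do.call(studyConfig, x)
}
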