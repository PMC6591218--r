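#' Simulation configuration for the synthetic coastal survey
#'
#' Describes a monthly, depth-stratified, size-fractionated sampling grid
#' (months x stations x depths x fractions) and the planted correlation
#' structure laid over it: `n_modules` groups of co-varying OTUs, each driven
#' by one latent factor that combines a depth gradient, one environmental
#' driver and a month effect, plus independent background OTUs.
#'
#' The defaults emulate the survey design the pipeline is meant for: 5 months
#' (Jul--Dec, no November), 6 stations, 3 depth layers and 3 size fractions,
#' i.e. the complete 5 x 6 x 3 x 3 grid of 270 fraction-samples.
#'
#' @param n_months Number of sampling months (1--5, labels taken from
#'   Jul/Aug/Sept/Oct/Dec in order).
#' @param n_stations Number of stations.
#' @param n_depths Number of depth layers (1--3, labels from
#'   surface/middle/bottom).
#' @param fractions Character vector of size-fraction labels (subset of
#'   FL/NP/MP).
#' @param n_modules Number of planted OTU modules.
#' @param otus_per_module OTUs per module (>= 2).
#' @param n_background_otus Independent background OTUs.
#' @param loading_mean Mean factor loading of non-hub module members
#'   (members draw 0.83--1.17x this value, so correlation strength varies
#'   across the module); the designated hub member gets 2.3x, which makes it
#'   the member most strongly coupled to — and hence most connected within —
#'   its module.
#' @param noise_sd SD of the per-OTU log-abundance noise around the module
#'   factor (natural-log scale). Also scales the hub-centred secondary
#'   factor loadings (0.7x for members, 2.4x for the hub), so `noise_sd = 0`
#'   collapses every module onto its primary factor exactly.
#' @param reads_per_sample Library size for the multinomial draw (>= 100).
#' @param env_link_strength Weight of the (standardised) environmental driver
#'   in each module's latent factor; 0 unlinks modules from the environment.
#' @param seed Base seed; per-operation streams are split from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_months = 5, n_stations = 6, n_depths = 3,
                       fractions = c("FL", "NP", "MP"),
                       n_modules = 6, otus_per_module = 10,
                       n_background_otus = 60,
                       loading_mean = 0.6, noise_sd = 0.5,
                       reads_per_sample = 10000,
                       env_link_strength = 0.5, seed = 1) {
  stopifnot(n_months >= 1, n_months <= length(MONTH_LEVELS),
            n_stations >= 1, n_depths >= 1, n_depths <= length(DEPTH_LEVELS),
            length(fractions) >= 1, all(fractions %in% FRACTION_LEVELS),
            n_modules >= 1, n_background_otus >= 0,
            noise_sd >= 0, reads_per_sample >= 100, loading_mean > 0)
  if (otus_per_module < 2)
    stop("each planted module needs at least 2 OTUs")
  structure(list(n_months = as.integer(n_months),
                 n_stations = as.integer(n_stations),
                 n_depths = as.integer(n_depths),
                 fractions = fractions,
                 n_modules = as.integer(n_modules),
                 otus_per_module = as.integer(otus_per_module),
                 n_background_otus = as.integer(n_background_otus),
                 loading_mean = loading_mean, noise_sd = noise_sd,
                 reads_per_sample = as.integer(reads_per_sample),
                 env_link_strength = env_link_strength,
                 seed = seed),
            class = "sim_config")
}

#' Sample grid implied by a simulation configuration
#'
#' @param config A [sim_config()].
#' @return Data frame with one row per fraction-sample: `sample_id`,
#'   `unit_id` (month_station_depth water sample shared by the fractions),
#'   `month`, `station`, `depth`, `fraction`.
#' @export
sample_grid <- function(config) {
  months <- MONTH_LEVELS[seq_len(config$n_months)]
  stations <- sprintf("St%02d", seq_len(config$n_stations))
  depths <- DEPTH_LEVELS[seq_len(config$n_depths)]
  g <- expand.grid(fraction = config$fractions, depth = depths,
                   station = stations, month = months,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, c("month", "station", "depth", "fraction")]
  g$unit_id <- paste(g$month, g$station, g$depth, sep = "_")
  g$sample_id <- paste(g$unit_id, g$fraction, sep = "_")
  g[, c("sample_id", "unit_id", "month", "station", "depth", "fraction")]
}

# depth-dependent environmental distributions: mean/sd per layer, plus the
# clipping windows observed in shallow coastal water. Middle values sit
# between surface and bottom.
env_param_table <- function() {
  list(
    temperature = list(mean = c(surface = 21.8, middle = 20.0, bottom = 18.2),
                       sd = c(4.5, 4.0, 3.4), clip = c(14.1, 29.7)),
    salinity = list(mean = c(surface = 32.1, middle = 32.8, bottom = 33.4),
                    sd = c(1.4, 1.2, 1.0), clip = c(29.0, 34.4)),
    NOx = list(mean = c(surface = 1.8, middle = 3.0, bottom = 4.5),
               sd = c(1.6, 2.2, 2.8),
               clip_by_depth = list(surface = c(0.02, 6.77),
                                    middle = c(0.02, 12.04),
                                    bottom = c(0.17, 12.04))),
    phosphate = list(mean = c(surface = 0.25, middle = 0.45, bottom = 0.65),
                     sd = c(0.15, 0.22, 0.30), clip = c(0.01, 3)),
    silicate = list(mean = c(surface = 5, middle = 9, bottom = 13),
                    sd = c(3, 4, 5), clip = c(0.1, 40)),
    DO = list(mean = c(surface = 8.5, middle = 7.5, bottom = 6.5),
              sd = c(1.0, 1.0, 1.0), clip = c(2, 14)),
    pH = list(mean = c(surface = 8.2, middle = 8.1, bottom = 8.0),
              sd = c(0.15, 0.13, 0.12), clip = c(7.5, 8.6)),
    chla = list(mean = c(surface = 2.5, middle = 2.0, bottom = 1.0),
                sd = c(1.2, 1.0, 0.6), clip = c(0.05, 20))
  )
}

#' Generate a synthetic environmental-parameter table
#'
#' One row per water sample (month x station x depth unit). Each variable is
#' drawn from a depth-dependent normal distribution and clipped to the range
#' observed in shallow coastal water (e.g. temperature 14.1--29.7 degC,
#' salinity 29.0--34.4 psu; NOx clipped per layer, 0.02--6.77 uM at the
#' surface and 0.17--12.04 uM at the bottom).
#'
#' @param config A [sim_config()].
#' @param seed Seed for this operation's RNG stream (default: split from
#'   `config$seed`).
#' @param sd_scale Multiplier on every variable's SD; 0 gives the layer means
#'   exactly (useful for degenerate-noise checks).
#' @return Data frame: `unit_id`, `month`, `station`, `depth` and the eight
#'   numeric variables (temperature, salinity, NOx, phosphate, silicate, DO,
#'   pH, chla).
#' @export
generate_env <- function(config, seed = split_seed(config$seed, "env"),
                         sd_scale = 1) {
  stopifnot(inherits(config, "sim_config"), sd_scale >= 0)
  g <- sample_grid(config)
  units <- g[!duplicated(g$unit_id),
             c("unit_id", "month", "station", "depth")]
  rownames(units) <- NULL
  pars <- env_param_table()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (v in names(pars)) {
    p <- pars[[v]]
    idx <- match(units$depth, DEPTH_LEVELS)
    x <- rnorm(nrow(units), mean = p$mean[idx], sd = p$sd[idx] * sd_scale)
    if (!is.null(p[["clip"]])) {
      x <- pmin(pmax(x, p[["clip"]][1]), p[["clip"]][2])
    } else {
      for (d in names(p$clip_by_depth)) {
        w <- units$depth == d
        x[w] <- pmin(pmax(x[w], p$clip_by_depth[[d]][1]),
                     p$clip_by_depth[[d]][2])
      }
    }
    units[[v]] <- x
  }
  units
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate planted-module OTU counts over an environmental table
#'
#' For each module m a latent factor over water-sample units,
#' \deqn{f_m(u) = \alpha_m d(u) + \beta z(\mathrm{driver}_m(u)) + \gamma_{m,
#' \mathrm{month}(u)} + \eta_u,}
#' standardised to unit variance, where d(u) is the depth code (0, 0.5, 1 for
#' surface/middle/bottom). Surface-preferring (S) modules get negative
#' alpha, middle/bottom (MB) modules positive alpha and whole-column (W)
#' modules alpha = 0; depth preferences and environmental drivers are
#' assigned cyclically. Each module also carries a secondary, hub-centred
#' factor `h_m` (unit-level standard normal). Member OTU i has log-abundance
#' `base_i + loading_i * f_m + hub_loading_i * h_m + eps` with
#' `eps ~ N(0, noise_sd)`; the hub member has the largest loading on both
#' factors, so it is the member most strongly correlated with the rest of
#' its module and hence its best-connected node. Background OTUs are
#' independent log-normals. Counts are drawn multinomially per sample with
#' total `reads_per_sample`, so columns are compositionally closed.
#'
#' @param config A [sim_config()].
#' @param env Environmental table from [generate_env()] on the same grid.
#' @param seed Seed for this operation's RNG stream (default: split from
#'   `config$seed`).
#' @return List with `otu` (an [otu_table()]), `meta` (the sample grid),
#'   `truth` (ground truth: `$otus` with module/hub/loading per OTU,
#'   `$modules` with depth preference and env driver per module) and
#'   `latent` (the pre-multinomial log-abundance matrix, OTU x sample).
#' @export
generate_counts <- function(config, env,
                            seed = split_seed(config$seed, "counts")) {
  stopifnot(inherits(config, "sim_config"))
  g <- sample_grid(config)
  if (!all(g$unit_id %in% env$unit_id))
    stop("env table does not cover the sample grid")
  if (config$otus_per_module < 2)
    stop("each planted module needs at least 2 OTUs")

  units <- env[match(unique(g$unit_id), env$unit_id), ]
  n_units <- nrow(units)
  depth_code <- c(surface = 0, middle = 0.5, bottom = 1)[units$depth]

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  prefs <- rep(c("S", "MB", "W"), length.out = config$n_modules)
  drivers <- rep(c("temperature", "NOx", "phosphate", "silicate", "salinity"),
                 length.out = config$n_modules)
  alpha <- c(S = -0.8, MB = 0.8, W = 0)[prefs]

  # latent factor per module over units
  f <- matrix(0, n_units, config$n_modules)
  for (m in seq_len(config$n_modules)) {
    drv <- units[[drivers[m]]]
    z <- if (sd(drv) > 0) (drv - mean(drv)) / sd(drv) else drv * 0
    month_eff <- rnorm(length(MONTH_LEVELS), 0, 0.6)
    fm <- alpha[m] * depth_code +
      config$env_link_strength * z +
      month_eff[match(units$month, MONTH_LEVELS)] +
      rnorm(n_units, 0, 0.5)
    f[, m] <- if (sd(fm) > 0) (fm - mean(fm)) / sd(fm) else fm
  }

  # second, hub-centred factor per module: the hub loads on it strongly,
  # members weakly, so hub-member correlations clear the detection threshold
  # comfortably while most member-member correlations sit below it. This is
  # what makes the planted hub the best-connected member of its module.
  h <- matrix(rnorm(n_units * config$n_modules), n_units, config$n_modules)

  K <- config$otus_per_module
  n_planted <- config$n_modules * K
  n_otus <- n_planted + config$n_background_otus
  otu_ids <- sprintf("OTU%04d", seq_len(n_otus))
  module_of <- c(rep(seq_len(config$n_modules), each = K),
                 rep(NA_integer_, config$n_background_otus))

  loading <- hub_loading <- noise <- numeric(n_otus)
  is_hub <- logical(n_otus)
  for (m in seq_len(config$n_modules)) {
    idx <- which(module_of == m)
    loading[idx] <- runif(K, 0.83, 1.17) * config$loading_mean
    hub_loading[idx] <- 0.7 * config$noise_sd
    noise[idx] <- config$noise_sd
    loading[idx[1]] <- 2.3 * config$loading_mean  # hub: largest loading
    hub_loading[idx[1]] <- 2.4 * config$noise_sd
    noise[idx[1]] <- 0.4 * config$noise_sd
    is_hub[idx[1]] <- TRUE
  }

  base <- rnorm(n_otus, 0, 0.5)
  unit_of_sample <- match(g$unit_id, units$unit_id)
  n_samples <- nrow(g)
  latent <- matrix(0, n_otus, n_samples,
                   dimnames = list(otu_ids, g$sample_id))
  for (i in seq_len(n_otus)) {
    m <- module_of[i]
    signal <- if (is.na(m)) rnorm(n_samples, 0, 1)
              else loading[i] * f[unit_of_sample, m] +
                   hub_loading[i] * h[unit_of_sample, m] +
                   rnorm(n_samples, 0, noise[i])
    latent[i, ] <- base[i] + signal
  }

  counts <- matrix(0L, n_otus, n_samples,
                   dimnames = list(otu_ids, g$sample_id))
  for (s in seq_len(n_samples)) {
    p <- exp(latent[, s] - max(latent[, s]))
    counts[, s] <- rmultinom(1, config$reads_per_sample, p / sum(p))[, 1]
  }

  truth <- list(
    otus = data.frame(otu_id = otu_ids, module = module_of,
                      hub = is_hub, loading = loading,
                      stringsAsFactors = FALSE),
    modules = data.frame(module = seq_len(config$n_modules),
                         depth_preference = prefs, env_driver = drivers,
                         stringsAsFactors = FALSE)
  )
  list(otu = otu_table(counts), meta = g, truth = truth, latent = latent)
}

#' Run the generator end to end
#'
#' Convenience wrapper: environment table then counts, from one config.
#'
#' @inheritParams generate_env
#' @return As [generate_counts()], plus `$env`.
#' @export
simulate_survey <- function(config = sim_config(), sd_scale = 1) {
  env <- generate_env(config, sd_scale = sd_scale)
  out <- generate_counts(config, env)
  out$env <- env
  out
}

#' Write ground truth as a key-value TSV
#'
#' @param truth `$truth` element from [generate_counts()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) {
  kv <- rbind(
    data.frame(key = paste0("module_of.", truth$otus$otu_id),
               value = ifelse(is.na(truth$otus$module), "none",
                              truth$otus$module)),
    data.frame(key = paste0("hub.", truth$otus$otu_id[truth$otus$hub]),
               value = "TRUE"),
    data.frame(key = paste0("depth_preference.", truth$modules$module),
               value = truth$modules$depth_preference),
    data.frame(key = paste0("env_driver.", truth$modules$module),
               value = truth$modules$env_driver)
  )
  write.table(kv, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
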