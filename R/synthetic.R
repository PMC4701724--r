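#' Conceptual mismatch scenario specification
#'
#' Parameters for one simulated observed/modeled pair illustrating a
#' canonical form of model (mis)fit: perfect fit, scale mismatch, inverse
#' variation, lack of correlation, trend mismatch, or a combination
#' (scale mismatch on a trend-flipped signal). Each scenario has a known
#' metric signature: e.g. scale mismatch leaves correlations at 1 while
#' driving modeling efficiency negative.
#'
#' @param kind One of `"perfect"`, `"scale_mismatch"`, `"inverse"`,
#'   `"uncorrelated"`, `"trend_mismatch"`, `"combined"`.
#' @param length Number of annual steps (>= 10; default 40, one step per
#'   year of a four-decade hindcast).
#' @param noise_sd Standard deviation of additive Gaussian observation
#'   noise around the base signal (default 0.5, about a quarter of the
#'   seasonal cycle amplitude).
#' @param scale_factor Multiplier applied to the modeled signal for the
#'   scale-mismatch kinds (default 2).
#' @param seed Integer RNG seed; always recorded in the output.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(kind, length = 40L, noise_sd = 0.5,
                          scale_factor = 2, seed = 1L) {
  kind <- match.arg(kind, SCENARIO_KINDS)
  length <- as.integer(length)
  if (length < 10L) stop("scenario length must be >= 10 years")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(kind = kind, length = length, noise_sd = noise_sd,
                 scale_factor = scale_factor, seed = as.integer(seed)),
            class = "scenario_spec")
}

SCENARIO_KINDS <- c("perfect", "scale_mismatch", "inverse", "uncorrelated",
                    "trend_mismatch", "combined")

# smooth base signal: positive level + linear trend (random magnitude and
# sign) + one sinusoidal cycle with random phase
scenario_base <- function(length) {
  t <- seq_len(length)
  slope <- stats::runif(1, 0.05, 0.15) * sample(c(-1, 1), 1)
  phase <- stats::runif(1, 0, 2 * pi)
  cycle_period <- stats::runif(1, 8, 15)
  base <- 10 + slope * t + 2 * sin(2 * pi * t / cycle_period + phase)
  list(base = base, slope = slope, phase = phase,
       cycle_period = cycle_period, t = t)
}

#' Generate a conceptual mismatch scenario
#'
#' Draws a smooth base signal (level + linear trend + sinusoid, random
#' phase and trend sign), sets the observations to the base plus Gaussian
#' noise, and derives the modeled series according to the scenario kind:
#' \describe{
#'   \item{perfect}{model = base signal.}
#'   \item{scale_mismatch}{model = `scale_factor` x base.}
#'   \item{inverse}{model = base reflected about its mean (ranks reversed).}
#'   \item{uncorrelated}{model = an independently redrawn base signal.}
#'   \item{trend_mismatch}{model = base with the trend slope sign flipped.}
#'   \item{combined}{model = `scale_factor` x trend-flipped base.}
#' }
#' Identical `(spec, seed)` always reproduce identical output.
#'
#' @param spec A [scenario_spec()].
#' @return An `eco_pair` (years numbered 1..length) carrying the spec as
#'   attribute `"spec"`.
#' @export
generate_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  with_seed(spec$seed, {
    sig <- scenario_base(spec$length)
    base <- sig$base
    obs <- base + stats::rnorm(spec$length, 0, spec$noise_sd)
    mod <- switch(spec$kind,
      perfect = base,
      scale_mismatch = spec$scale_factor * base,
      inverse = 2 * mean(base) - base,
      uncorrelated = scenario_base(spec$length)$base,
      trend_mismatch = base - 2 * sig$slope * sig$t,
      combined = spec$scale_factor * (base - 2 * sig$slope * sig$t)
    )
    pair <- structure(
      list(series_id = paste0("scenario_", spec$kind), category = "biomass",
           years = sig$t, obs = obs, mod = mod, n = spec$length),
      class = "eco_pair")
    attr(pair, "spec") <- spec
    pair
  })
}

#' Synthetic ecosystem configuration
#'
#' The stated world the generator emulates: 30 functional groups in a
#' guild mix dominated by fish and benthos, annual series 1964-2013, seal
#' series starting 1981, whale series 1990 and satellite primary
#' production 1998, lognormal survey observation error with CV 0.3, and a
#' per-group model-skill knob (`"high"`, `"medium"`, `"noise_only"`)
#' controlling how closely modeled output tracks latent truth.
#'
#' @param n_groups Number of functional groups (default 30).
#' @param guild_mix Named numeric proportions over the seven guilds; must
#'   produce at least one commercial fish group.
#' @param years Integer year range (default `1964:2013`).
#' @param forecast_split Last year of the hindcast (default 2004).
#' @param skill Character scalar or vector (recycled to `n_groups`) of
#'   per-group skill levels.
#' @param obs_cv Coefficient of variation of survey observation error.
#' @param onsets Named list of first observed years:
#'   `mammal_seal`, `mammal_whale` (biomass) and `primary_production`.
#' @param harvest_rate Optional numeric vector of per-group harvest rates;
#'   drawn `U(0.05, 0.25)` for commercial groups when `NULL`. A rate
#'   >= 1 is infeasible and errors.
#' @param seed Integer RNG seed.
#' @return An `ecosystem_config` list.
#' @export
ecosystem_config <- function(n_groups = 30L,
                             guild_mix = c(demersal_fish = 0.30,
                                           pelagic_fish = 0.20,
                                           benthos = 0.25,
                                           mammal_seal = 0.05,
                                           mammal_whale = 0.05,
                                           seabird = 0.05,
                                           other = 0.10),
                             years = 1964:2013,
                             forecast_split = 2004L,
                             skill = "high",
                             obs_cv = 0.3,
                             onsets = list(mammal_seal = 1981L,
                                           mammal_whale = 1990L,
                                           primary_production = 1998L),
                             harvest_rate = NULL,
                             seed = 1L) {
  n_groups <- as.integer(n_groups)
  stopifnot(n_groups >= 3L, length(years) >= 10L, obs_cv >= 0)
  stopifnot(all(names(guild_mix) %in% ECO_GUILDS), all(guild_mix >= 0),
            sum(guild_mix) > 0)
  skill <- match.arg(skill, c("high", "medium", "noise_only"),
                     several.ok = TRUE)
  skill <- rep_len(skill, n_groups)
  if (!is.null(harvest_rate) && any(harvest_rate >= 1))
    stop("infeasible harvest rate >= 1")
  structure(list(n_groups = n_groups, guild_mix = guild_mix,
                 years = as.integer(years),
                 forecast_split = as.integer(forecast_split),
                 skill = skill, obs_cv = obs_cv, onsets = onsets,
                 harvest_rate = harvest_rate, seed = as.integer(seed)),
            class = "ecosystem_config")
}

# deterministic allocation of groups to guilds from the mix proportions,
# guaranteeing at least one commercial (demersal fish) group
allocate_guilds <- function(n, mix) {
  mix <- mix / sum(mix)
  counts <- floor(mix * n)
  short <- n - sum(counts)
  if (short > 0) {
    frac <- mix * n - counts
    bump <- order(frac, decreasing = TRUE)[seq_len(short)]
    counts[bump] <- counts[bump] + 1
  }
  if (counts["demersal_fish"] == 0) {
    donor <- which.max(counts)
    counts[donor] <- counts[donor] - 1
    counts["demersal_fish"] <- 1
  }
  rep(names(counts), counts)
}

#' Generate a synthetic ecosystem with known ground truth
#'
#' Every group's latent "true" biomass follows a logistic-growth-with-
#' harvest recursion with lognormal process noise:
#' `B[t+1] = (B[t] + r B[t](1 - B[t]/K) - C[t]) * exp(eps)`, with
#' `C[t] = h B[t]` for commercial groups. Observed biomass is truth times
#' lognormal observation error (given CV) and is passed through the survey
#' swept-area expansion to attach 95% confidence bands. Observed landings
#' are the true catch with small reporting error, capped at the true
#' biomass. Modeled series are the truth distorted per the skill knob:
#' `high` adds small multiplicative noise, `medium` adds larger noise plus
#' a mild multiplicative scale drift, and `noise_only` substitutes an
#' independently generated trajectory. Category-specific onsets truncate
#' the observed seal, whale and primary-production records.
#'
#' @param config An [ecosystem_config()].
#' @return A list with elements `dataset` (an [ecosystem_dataset()]),
#'   `truth` (latent biomass matrix, per-group parameters, the config) and
#'   `biomass_ci` (per-year swept-area confidence bands for observed
#'   biomass).
#' @export
generate_ecosystem <- function(config) {
  stopifnot(inherits(config, "ecosystem_config"))
  with_seed(config$seed, {
    n <- config$n_groups
    yrs <- config$years
    ny <- length(yrs)
    guild <- allocate_guilds(n, config$guild_mix)
    gid <- sprintf("G%02d", seq_len(n))
    is_fish <- guild %in% c("demersal_fish", "pelagic_fish")
    is_comm <- (is_fish & stats::runif(n) < 0.8) |
      (guild == "benthos" & stats::runif(n) < 0.5)
    if (!any(is_comm & is_fish)) is_comm[which(is_fish)[1]] <- TRUE
    is_tep <- guild %in% c("mammal_seal", "mammal_whale", "seabird")
    tl <- numeric(n)
    tl[guild == "demersal_fish"] <- stats::runif(sum(guild == "demersal_fish"), 3.5, 4.5)
    tl[guild == "pelagic_fish"] <- stats::runif(sum(guild == "pelagic_fish"), 3.0, 4.2)
    tl[guild == "benthos"] <- stats::runif(sum(guild == "benthos"), 2.0, 3.0)
    tl[guild == "mammal_seal"] <- stats::runif(sum(guild == "mammal_seal"), 4.2, 5.0)
    tl[guild == "mammal_whale"] <- stats::runif(sum(guild == "mammal_whale"), 3.2, 4.2)
    tl[guild == "seabird"] <- stats::runif(sum(guild == "seabird"), 3.5, 4.5)
    tl[guild == "other"] <- stats::runif(sum(guild == "other"), 2.0, 4.0)
    price <- ifelse(is_comm, exp(stats::rnorm(n, log(1500), 0.5)), 0)

    k_scale <- c(demersal_fish = 1e5, pelagic_fish = 2e5, benthos = 1.5e5,
                 mammal_seal = 1e4, mammal_whale = 2e4, seabird = 2e3,
                 other = 5e4)
    K <- k_scale[guild] * exp(stats::rnorm(n, 0, 0.4))
    r <- ifelse(guild %in% c("mammal_seal", "mammal_whale"),
                stats::runif(n, 0.05, 0.15), stats::runif(n, 0.3, 0.8))
    h <- config$harvest_rate %||% ifelse(is_comm, stats::runif(n, 0.05, 0.25), 0)
    h <- rep_len(h, n)
    if (any(h >= 1)) stop("infeasible harvest rate >= 1")

    # logistic growth with harvest around a slowly varying carrying
    # capacity K_t (environmentally forced, multi-decadal), plus lognormal
    # process noise; K_t constant for recovering mammal populations, whose
    # signal is the slow rebuild from a depleted starting state instead
    run_traj <- function(K, r, h, b0_frac, ny, proc_sd = 0.1,
                         forced = TRUE) {
      if (forced) {
        amp <- stats::runif(1, 0.1, 0.25)
        per <- stats::runif(1, 20, 40)
        phase <- stats::runif(1, 0, 2 * pi)
        Kt <- K * exp(amp * sin(2 * pi * seq_len(ny) / per + phase))
      } else {
        Kt <- rep(K, ny)
      }
      B <- numeric(ny); C <- numeric(ny)
      B[1] <- Kt[1] * b0_frac
      for (t in seq_len(ny)) {
        C[t] <- h * B[t]
        if (t < ny) {
          eps <- stats::rnorm(1, 0, proc_sd)
          nxt <- (B[t] + r * B[t] * (1 - B[t] / Kt[t]) - C[t]) * exp(eps)
          B[t + 1] <- max(nxt, Kt[t] * 1e-3)
        }
      }
      list(B = B, C = C)
    }

    A_total <- 293000   # shelf survey area, km^2
    a_tow <- 0.01       # swept area per tow, km^2
    true_B <- matrix(NA_real_, ny, n, dimnames = list(yrs, gid))
    rows_bio <- list(); rows_lan <- list(); rows_ci <- list()
    # interannual process variability: recruitment-scale for fish and
    # invertebrates, small for long-lived mammals whose signal is the slow
    # recovery from a depleted initial state
    is_mammal <- guild %in% c("mammal_seal", "mammal_whale")
    for (i in seq_len(n)) {
      b0 <- if (is_mammal[i]) stats::runif(1, 0.1, 0.3)
            else stats::runif(1, 0.5, 1.05)
      tr <- run_traj(K[i], r[i], h[i], b0, ny,
                     proc_sd = if (is_mammal[i]) 0.05 else 0.25,
                     forced = !is_mammal[i])
      true_B[, i] <- tr$B
      obs_err <- exp(stats::rnorm(ny, 0, sqrt(log(1 + config$obs_cv^2))))
      obs_B <- tr$B * obs_err
      # attach design-based confidence bands via the swept-area expansion:
      # back out the implied mean catch per tow, expand with q = 1
      ci_lo <- ci_hi <- numeric(ny)
      for (t in seq_len(ny)) {
        m_tow <- obs_B[t] * a_tow / A_total
        v_tow <- (config$obs_cv * m_tow)^2
        est <- expand_to_swept_area(m_tow, v_tow, q = 1, A = A_total, a = a_tow)
        ci_lo[t] <- est$ci_low; ci_hi[t] <- est$ci_high
      }
      skill_i <- config$skill[i]
      mod_B <- switch(skill_i,
        high = tr$B * exp(stats::rnorm(ny, 0, 0.10)),
        medium = tr$B * exp(stats::rnorm(ny, 0, 0.30)) *
          exp(stats::runif(1, -0.02, 0.02) * seq_len(ny)),
        noise_only = run_traj(K[i] * exp(stats::rnorm(1, 0, 0.4)),
                              stats::runif(1, 0.3, 0.8), h[i],
                              stats::runif(1, 0.5, 1.05), ny,
                              proc_sd = 0.25, forced = TRUE)$B
      )
      obs_C <- pmin(tr$C * exp(stats::rnorm(ny, 0, 0.05)), tr$B)
      mod_C <- h[i] * mod_B
      onset <- switch(guild[i],
        mammal_seal = config$onsets$mammal_seal %||% yrs[1],
        mammal_whale = config$onsets$mammal_whale %||% yrs[1],
        yrs[1])
      keep <- yrs >= onset
      rows_bio[[length(rows_bio) + 1L]] <- data.frame(
        group_id = gid[i], source = "observed", year = yrs[keep],
        value = obs_B[keep], stringsAsFactors = FALSE)
      rows_bio[[length(rows_bio) + 1L]] <- data.frame(
        group_id = gid[i], source = "modeled", year = yrs,
        value = mod_B, stringsAsFactors = FALSE)
      rows_ci[[length(rows_ci) + 1L]] <- data.frame(
        group_id = gid[i], year = yrs[keep], ci_low = ci_lo[keep],
        ci_high = ci_hi[keep], stringsAsFactors = FALSE)
      if (is_comm[i]) {
        rows_lan[[length(rows_lan) + 1L]] <- data.frame(
          group_id = gid[i], source = "observed", year = yrs,
          value = obs_C, stringsAsFactors = FALSE)
        rows_lan[[length(rows_lan) + 1L]] <- data.frame(
          group_id = gid[i], source = "modeled", year = yrs,
          value = mod_C, stringsAsFactors = FALSE)
      }
    }

    # primary production: smooth forced cycle, observed by satellite only
    # from the configured onset year
    t_idx <- seq_len(ny)
    pp_true <- 5e6 * exp(0.1 * sin(2 * pi * t_idx / 11) +
                         stats::rnorm(ny, 0, 0.05))
    pp_obs <- pp_true * exp(stats::rnorm(ny, 0, 0.1))
    pp_mod <- pp_true * exp(stats::rnorm(ny, 0, 0.1))
    pp_onset <- config$onsets$primary_production %||% yrs[1]
    pp <- rbind(
      data.frame(source = "observed", year = yrs[yrs >= pp_onset],
                 value = pp_obs[yrs >= pp_onset], stringsAsFactors = FALSE),
      data.frame(source = "modeled", year = yrs, value = pp_mod,
                 stringsAsFactors = FALSE))

    metadata <- data.frame(
      group_id = gid, name = paste0("group_", seq_len(n)), guild = guild,
      is_fish = is_fish, is_commercial = is_comm, is_tep = is_tep,
      trophic_level = tl, price_per_ton = price, stringsAsFactors = FALSE)
    dataset <- ecosystem_dataset(
      biomass = do.call(rbind, rows_bio),
      landings = do.call(rbind, rows_lan),
      primary_production = pp,
      metadata = metadata)
    list(dataset = dataset,
         truth = list(biomass = true_B,
                      params = data.frame(group_id = gid, guild = guild,
                                          K = K, r = r, harvest_rate = h,
                                          skill = config$skill,
                                          stringsAsFactors = FALSE),
                      config = config),
         biomass_ci = do.call(rbind, rows_ci))
  })
}
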