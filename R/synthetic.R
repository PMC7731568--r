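#' Generate a synthetic world of training and mystery cities
#'
#' Draws city locations over the globe and splits them into a training
#' panel and a disjoint "mystery" panel of never-sampled origins — the
#' open-set condition. Continents are simple longitude/latitude blocks so
#' continent-level assessment works without geographic data files.
#'
#' @param n_train_cities number of training cities (at least 3, so a
#'   model can always be fit and leave-one-city-out stays meaningful).
#' @param n_mystery_cities number of held-out new-origin cities.
#' @param samples_per_city either a single integer or a length-2 range
#'   from which each city's sample count is drawn uniformly.
#' @param seed integer RNG seed; the same seed reproduces the panels
#'   exactly.
#' @param n_single_end how many training cities use the single-end 125 bp
#'   protocol instead of paired-end 150 bp (the protocol-batch condition).
#' @param n_single_end_mystery how many mystery cities are single-end —
#'   the heterogeneous-protocol open-set condition, where a new-origin
#'   city shares its protocol artifact with a training city.
#' @return list with `train` and `mystery` city panels, each a data.frame
#'   with `city_id`, `name`, `latitude`, `longitude`, `continent`,
#'   `protocol`, `n_samples`.
#' @export
generate_world <- function(n_train_cities = 15, n_mystery_cities = 8,
                           samples_per_city = 18, seed,
                           n_single_end = 0,
                           n_single_end_mystery = 0) {
  if (n_train_cities < 3)
    stop("`n_train_cities` must be at least 3")
  if (n_mystery_cities < 0)
    stop("`n_mystery_cities` must be nonnegative")
  if (any(samples_per_city < 2))
    stop("`samples_per_city` must be at least 2")
  if (missing(seed)) stop("`seed` is required")
  if (n_single_end > n_train_cities)
    stop("more single-end cities than training cities")
  set.seed(seed)
  n <- n_train_cities + n_mystery_cities
  lat <- stats::runif(n, -55, 65)
  lon <- stats::runif(n, -170, 170)
  ns <- if (length(samples_per_city) == 1) rep(samples_per_city, n)
        else sample(samples_per_city[1]:samples_per_city[2], n,
                    replace = TRUE)
  mk <- function(idx, prefix) {
    ids <- sprintf("%s%02d", prefix, seq_along(idx))
    data.frame(
      city_id = ids,
      name = sprintf("%s City %02d",
                     if (prefix == "TC") "Train" else "Mystery",
                     seq_along(idx)),
      latitude = lat[idx], longitude = lon[idx],
      continent = continent_block(lat[idx], lon[idx]),
      protocol = "paired_150",
      n_samples = ns[idx],
      stringsAsFactors = FALSE)
  }
  train <- mk(seq_len(n_train_cities), "TC")
  mystery <- if (n_mystery_cities > 0)
    mk(n_train_cities + seq_len(n_mystery_cities), "MC")
  else train[0, ]
  if (n_single_end > 0) {
    picked <- seq(n_train_cities, by = -1, length.out = n_single_end)
    train$protocol[picked] <- "single_125"
  }
  if (n_single_end_mystery > 0) {
    if (n_single_end_mystery > n_mystery_cities)
      stop("more single-end mystery cities than mystery cities")
    picked <- seq(n_mystery_cities, by = -1,
                  length.out = n_single_end_mystery)
    mystery$protocol[picked] <- "single_125"
  }
  list(train = train, mystery = mystery)
}

# small deterministic hash of a city id, used to derive its RNG stream
city_seed_offset <- function(city_id) {
  sum(utf8ToInt(city_id) * (31L^(seq_len(nchar(city_id)) - 1))) %% 1000003L
}

# 6 pseudo-continents: 3 longitude bands x 2 latitude bands
continent_block <- function(lat, lon) {
  ew <- cut(lon, breaks = c(-180, -60, 60, 180),
            labels = c("West", "Central", "East"))
  ns <- ifelse(lat >= 5, "North", "South")
  paste0(ns, ew)
}

#' Ground truth for the synthetic count generator
#'
#' Fixes everything the generator needs to plant a recoverable
#' geographic signal: a random species-to-genus-to-family taxonomy, log2
#' baselines, a set of informative taxa whose expected log2 abundance
#' changes linearly with city latitude (and, more weakly, longitude) —
#' the latitudinal-gradient structure reported for real microbiomes —
#' plus city-specific signatures, zero inflation and overdispersion.
#'
#' @param n_species,n_genera,n_families taxonomy sizes; species are
#'   mapped to genera and genera to families uniformly at random under
#'   the seed.
#' @param n_informative number of species carrying geographic signal.
#' @param lat_slope absolute latitude slope, log2-abundance units per
#'   degree; informative taxa alternate sign.
#' @param long_slope absolute longitude slope (same units).
#' @param city_effect_sd standard deviation of per-(taxon, city) log2
#'   signature effects; 0 removes city identity beyond geography.
#' @param zero_inflation_prob probability a (taxon, sample) count is a
#'   structural zero, mimicking detection dropouts.
#' @param library_size_range integer pair; per-sample library sizes are
#'   drawn uniformly from this range.
#' @param batch_shift log2 shift applied to half the taxa of a single-end
#'   protocol city by [generate_batch_city()].
#' @param dispersion negative binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param seed integer seed governing the taxonomy, baselines, slopes and
#'   all count draws.
#' @return list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(n_species = 200, n_genera = 60,
                            n_families = 25, n_informative = 10,
                            lat_slope = 0.05, long_slope = 0.02,
                            city_effect_sd = 1,
                            zero_inflation_prob = 0.05,
                            library_size_range = c(5e4, 2e5),
                            batch_shift = 6, dispersion = 0.5,
                            seed) {
  if (missing(seed)) stop("`seed` is required")
  stopifnot(n_informative <= n_species,
            zero_inflation_prob >= 0, zero_inflation_prob <= 1,
            length(library_size_range) == 2,
            all(library_size_range > 0),
            is.finite(lat_slope), is.finite(long_slope),
            city_effect_sd >= 0, dispersion > 0)
  set.seed(seed)
  species <- sprintf("sp%03d", seq_len(n_species))
  genera <- sprintf("g%02d", seq_len(n_genera))
  families <- sprintf("f%02d", seq_len(n_families))
  # every genus/family is hit at least once, remainder at random
  sp2g <- genera[c(seq_len(n_genera),
                   sample.int(n_genera, n_species - n_genera,
                              replace = TRUE))]
  g2f <- families[c(seq_len(n_families),
                    sample.int(n_families, n_genera - n_families,
                               replace = TRUE))]
  names(g2f) <- genera
  taxonomy <- data.frame(taxon_id = species, rank = "species",
                         genus = sp2g, family = unname(g2f[sp2g]),
                         stringsAsFactors = FALSE)
  informative <- sort(sample(species, n_informative))
  lat_slopes <- stats::setNames(rep(0, n_species), species)
  long_slopes <- lat_slopes
  # orthogonal sign patterns (period 2 vs period 4) so latitude and
  # longitude effects are identifiable, not confounded
  lat_slopes[informative] <- rep_len(c(1, -1), n_informative) * lat_slope
  long_slopes[informative] <-
    rep_len(c(1, 1, -1, -1), n_informative) * long_slope
  baselines <- stats::setNames(stats::rnorm(n_species, 0, 2), species)
  # informative taxa get a fixed mid-abundance baseline: a log2-linear
  # gradient spanning ~6 log2 units across the globe is only observable
  # if the taxon stays above the detection floor at its low end
  baselines[informative] <- 3
  structure(list(taxonomy = taxonomy,
                 informative_taxa = informative,
                 latitude_slopes = lat_slopes,
                 longitude_slopes = long_slopes,
                 baselines = baselines,
                 city_effect_sd = city_effect_sd,
                 zero_inflation_prob = zero_inflation_prob,
                 library_size_range = library_size_range,
                 batch_shift = batch_shift,
                 dispersion = dispersion,
                 seed = seed),
            class = "synthetic_truth")
}

#' Generate synthetic count tables for a city panel
#'
#' For taxon t in city c, the expected log2 abundance is
#' baseline_t + lat_slope_t * lat_c + long_slope_t * lon_c +
#' cityeffect_tc. Expected abundances are converted to per-sample
#' multinomial-style proportions, scaled to a uniformly drawn library
#' size, thinned by independent structural zeros, and drawn from a
#' negative binomial per (taxon, sample). Genus and family tables are
#' exact column sums of the species table by lineage.
#'
#' @param panel a city panel data.frame from [generate_world()].
#' @param truth a [synthetic_truth()] object.
#' @return list with `species`, `genus`, `family` ([taxa_count_table()]s)
#'   and `metadata` (one row per sample: `sample_id`, `city`,
#'   `latitude`, `longitude`, `continent`, `paired_end`,
#'   `read_length_bp`).
#' @export
generate_counts <- function(panel, truth) {
  generate_counts_impl(panel, truth, batch = FALSE)
}

#' Generate counts with a protocol batch artifact
#'
#' Like [generate_counts()], but the panel's single single-end city gets
#' `truth$batch_shift` added to the expected log2 abundance of a random
#' half of all taxa — a systematic artifact standing in for the
#' shorter-read, single-end protocol's different detection profile.
#'
#' @inheritParams generate_counts
#' @return As [generate_counts()].
#' @export
generate_batch_city <- function(panel, truth) {
  n_se <- sum(panel$protocol == "single_125")
  if (n_se != 1)
    stop("panel must contain exactly one single_125 city, found ", n_se)
  generate_counts_impl(panel, truth, batch = TRUE)
}

generate_counts_impl <- function(panel, truth, batch) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!nrow(panel)) stop("empty city panel")
  if (!all(c("city_id", "latitude", "longitude", "n_samples") %in%
           names(panel)))
    stop("panel is missing required columns")
  set.seed(truth$seed)
  species <- truth$taxonomy$taxon_id
  n_t <- length(species)
  # the batch taxon subset is drawn first, before any panel-dependent
  # draws, so the same truth yields the same protocol artifact for every
  # panel (and batch_shift = 0 output is bit-identical to the clean path)
  batch_taxa <- sample(species, floor(n_t / 2))
  # per-(taxon, city) signature effects, seeded from the city id so a
  # city keeps its signature across panels while distinct cities --
  # including train vs mystery -- never share one
  E <- vapply(seq_len(nrow(panel)), function(ci) {
    set.seed((truth$seed + city_seed_offset(panel$city_id[ci])) %%
               .Machine$integer.max)
    stats::rnorm(n_t, 0, truth$city_effect_sd)
  }, numeric(n_t))
  dimnames(E) <- list(species, panel$city_id)
  # count sampling resumes from a panel-specific stream
  set.seed((truth$seed + 7L +
              sum(vapply(panel$city_id, city_seed_offset, 0))) %%
             .Machine$integer.max)
  log2mu <- truth$baselines +
    outer(truth$latitude_slopes, panel$latitude) +
    outer(truth$longitude_slopes, panel$longitude) + E
  if (batch) {
    se_city <- which(panel$protocol == "single_125")
    log2mu[batch_taxa, se_city] <- log2mu[batch_taxa, se_city] +
      truth$batch_shift
  }
  props <- 2^log2mu
  props <- sweep(props, 2, colSums(props), "/")
  n_total <- sum(panel$n_samples)
  counts <- matrix(0L, n_total, n_t)
  meta <- vector("list", nrow(panel))
  row <- 0L
  size <- 1 / truth$dispersion
  for (ci in seq_len(nrow(panel))) {
    n_i <- panel$n_samples[ci]
    libs <- round(stats::runif(n_i, truth$library_size_range[1],
                               truth$library_size_range[2]))
    for (s in seq_len(n_i)) {
      row <- row + 1L
      mu <- props[, ci] * libs[s]
      if (truth$zero_inflation_prob > 0)
        mu[stats::runif(n_t) < truth$zero_inflation_prob] <- 0
      counts[row, ] <- ifelse(mu == 0, 0L,
                              stats::rnbinom(n_t, size = size, mu = mu))
    }
    meta[[ci]] <- data.frame(
      sample_id = sprintf("%s_s%02d", panel$city_id[ci], seq_len(n_i)),
      city = panel$city_id[ci],
      latitude = panel$latitude[ci],
      longitude = panel$longitude[ci],
      continent = panel$continent[ci],
      paired_end = panel$protocol[ci] == "paired_150",
      read_length_bp = if (panel$protocol[ci] == "paired_150") 150L
                       else 125L,
      stringsAsFactors = FALSE)
  }
  metadata <- do.call(rbind, meta)
  dimnames(counts) <- list(metadata$sample_id, species)
  sp_table <- taxa_count_table(counts, truth$taxonomy, rank = "species")
  list(species = sp_table,
       genus = aggregate_taxa(sp_table, "genus"),
       family = aggregate_taxa(sp_table, "family"),
       metadata = metadata)
}
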