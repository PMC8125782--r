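#' @title Synthetic prescription records
#' @description
#' Generates patient-level dispensation records with the statistical
#' structure administrative prescription databases show: a slight female
#' majority, three age strata (children/young adults, working-age, elderly)
#' with the elderly receiving the bulk of prescriptions, heavy-tailed
#' (Zipf-like) drug popularity — a few drugs dispensed to a large share of
#' the cohort, many to a single patient — and non-random co-prescription
#' planted as drug "modules": small sets of level-5 codes that members of a
#' latent patient group receive together, creating positive phi correlation
#' within the module and none across modules.
#'
#' The defaults encode the study conditions of a one-year Italian local
#' health unit cohort: 54.7% female patients; 11.9% / 50.0% / 38.1% of
#' patients and 2.4% / 30.1% / 67.5% of prescriptions in the 0-21 / 22-64 /
#' 65+ strata (hence stratum mean prescription counts 3.03 / 9.03 / 26.58,
#' for an overall mean of 15 per patient); an 800-code level-5 catalog.
#' @name synthetic_records
NULL

#' Simulation configuration
#'
#' @param n_patients cohort size.
#' @param female_fraction probability a patient is female.
#' @param age_stratum_weights probabilities of the 0-21 / 22-64 / 65+
#'   strata; must sum to 1.
#' @param prescriptions_per_patient per-stratum Poisson means of the number
#'   of dispensation events per patient.
#' @param catalog_size number of distinct level-5 codes in the drug catalog.
#' @param popularity_exponent Zipf exponent of drug popularity (larger =
#'   heavier concentration on the top drugs).
#' @param modules list of planted co-prescription modules, each a list with
#'   `size` (number of codes), `rate` (probability a patient belongs) and
#'   `boost` (probability a member receives each module code). Use `list()`
#'   for no planted structure.
#' @param window_start,window_end observation window (dispensation dates are
#'   uniform within it).
#' @return a `SimConfig` list (validated).
#' @export
simConfig <- function(n_patients = 2000L,
                      female_fraction = 0.547,
                      age_stratum_weights = c(0.119, 0.500, 0.381),
                      prescriptions_per_patient = c(3.03, 9.03, 26.58),
                      catalog_size = 800L,
                      popularity_exponent = 1.3,
                      modules = list(
                        list(size = 4L, rate = 0.08, boost = 0.75),
                        list(size = 4L, rate = 0.08, boost = 0.75),
                        list(size = 4L, rate = 0.08, boost = 0.75)
                      ),
                      window_start = "2018-07-01",
                      window_end = "2019-06-30") {
  stopifnot(n_patients >= 1,
            female_fraction >= 0, female_fraction <= 1,
            length(age_stratum_weights) == 3L,
            all(age_stratum_weights >= 0),
            abs(sum(age_stratum_weights) - 1) < 1e-8,
            length(prescriptions_per_patient) == 3L,
            all(prescriptions_per_patient > 0),
            catalog_size >= 1, popularity_exponent > 0)
  structure(list(
    n_patients = as.integer(n_patients),
    female_fraction = female_fraction,
    age_stratum_weights = age_stratum_weights,
    prescriptions_per_patient = prescriptions_per_patient,
    catalog_size = as.integer(catalog_size),
    popularity_exponent = popularity_exponent,
    modules = modules,
    window_start = as.Date(window_start),
    window_end = as.Date(window_end)
  ), class = "SimConfig")
}

#' Generate a synthetic level-5 ATC catalog
#'
#' Draws syntactically valid, distinct level-5 codes. The hierarchy is made
#' non-trivial on purpose: codes are assembled from small pools of
#' therapeutic (2-digit), pharmacological (letter), chemical (letter) and
#' substance (2-digit) components within each anatomical group, so that
#' projecting the catalog to coarser ATC levels genuinely merges codes.
#' When `size >= 14` all 14 anatomical groups are represented.
#'
#' @param size number of codes.
#' @return character vector of `size` distinct valid level-5 codes.
#' @export
generateCatalog <- function(size) {
  size <- as.integer(size)
  stopifnot(size >= 1L)
  # component pools per group keep the hierarchy shallow and collision-rich
  therapeutic <- sprintf("%02d", 1:8)
  pharmacological <- c("A", "B", "C")
  chemical <- c("A", "B")
  substance <- sprintf("%02d", 1:16)
  space <- 14L * length(therapeutic) * length(pharmacological) *
    length(chemical) * length(substance)
  if (size > space) {
    stop("catalog_size ", size, " exceeds the generator's code space (",
         space, ")", call. = FALSE)
  }
  groups <- if (size >= 14L) {
    c(.ATC_GROUPS, sample(.ATC_GROUPS, size - 14L, replace = TRUE))
  } else {
    sample(.ATC_GROUPS, size)
  }
  codes <- character(0)
  need <- size
  grp <- groups
  while (need > 0L) {
    cand <- paste0(grp,
                   sample(therapeutic, need, replace = TRUE),
                   sample(pharmacological, need, replace = TRUE),
                   sample(chemical, need, replace = TRUE),
                   sample(substance, need, replace = TRUE))
    keep <- !duplicated(cand) & !cand %in% codes
    codes <- c(codes, cand[keep])
    grp <- grp[!keep]
    need <- length(grp)
  }
  codes
}

#' Generate synthetic prescription records
#'
#' Draws a cohort per the configuration: sex and age stratum per patient,
#' birth year uniform within the stratum's age range at the window-end
#' index date, a Poisson number of dispensation events with the stratum's
#' mean, each event's drug sampled from a Zipf popularity distribution over
#' the catalog. Patients belonging to a planted module additionally receive
#' each of the module's codes with probability `boost`, creating known
#' positive within-module phi. Module codes are taken from the tail of the
#' popularity ranking so the plant is not confounded with popularity.
#'
#' Call [set.seed()] before this function for reproducibility.
#'
#' @param cfg a `SimConfig` from [simConfig].
#' @param catalog optional pre-built level-5 catalog (character vector); when
#'   given it replaces the generated one, so several cohorts can share a
#'   common drug universe. Its length overrides `cfg$catalog_size`.
#' @return a list with `records` (data.frame in the [loadRecords] schema),
#'   `catalog` (the level-5 codes) and `modules` (list of code sets
#'   actually planted).
#' @export
generateRecords <- function(cfg, catalog = NULL) {
  stopifnot(inherits(cfg, "SimConfig"))
  n <- cfg$n_patients
  if (is.null(catalog)) {
    catalog <- generateCatalog(cfg$catalog_size)
  } else {
    catalog <- parseATC(catalog)
    stopifnot(all(atcLevel(catalog) == 5L), !anyDuplicated(catalog))
    cfg$catalog_size <- length(catalog)
  }
  if (length(catalog) == 0L) stop("empty catalog", call. = FALSE)

  # Zipf popularity over popularity rank
  pop <- (seq_len(cfg$catalog_size))^(-cfg$popularity_exponent)
  pop <- pop / sum(pop)

  # reserve tail-rank codes for the planted modules
  mod_sizes <- vapply(cfg$modules, function(m) as.integer(m$size), integer(1))
  if (sum(mod_sizes) > cfg$catalog_size) {
    stop("planted modules need more codes than the catalog holds", call. = FALSE)
  }
  tail_ranks <- rev(seq_len(cfg$catalog_size))
  module_codes <- list()
  used <- 0L
  for (m in seq_along(cfg$modules)) {
    idx <- tail_ranks[(used + 1L):(used + mod_sizes[m])]
    module_codes[[m]] <- catalog[idx]
    used <- used + mod_sizes[m]
  }

  pid <- sprintf("P%06d", seq_len(n))
  sex <- ifelse(stats::runif(n) < cfg$female_fraction, "F", "M")
  stratum <- sample.int(3L, n, replace = TRUE, prob = cfg$age_stratum_weights)
  index_year <- as.integer(format(cfg$window_end, "%Y"))
  age_lo <- c(0L, 22L, 65L)[stratum]
  age_hi <- c(21L, 64L, 100L)[stratum]
  age <- age_lo + floor(stats::runif(n) * (age_hi - age_lo + 1L))
  birth_year <- index_year - as.integer(age)

  n_rx <- stats::rpois(n, cfg$prescriptions_per_patient[stratum])

  rec_pid <- rep(pid, n_rx)
  rec_idx <- rep(seq_len(n), n_rx)
  drug <- catalog[sample.int(cfg$catalog_size, sum(n_rx), replace = TRUE,
                             prob = pop)]

  # planted modules: members receive each module code with prob boost
  for (m in seq_along(cfg$modules)) {
    member <- stats::runif(n) < cfg$modules[[m]]$rate
    if (!any(member)) next
    take <- matrix(stats::runif(sum(member) * mod_sizes[m]) <
                     cfg$modules[[m]]$boost,
                   nrow = sum(member), ncol = mod_sizes[m])
    who <- which(member)
    add_pat <- rep(who, times = rowSums(take))
    add_code <- unlist(apply(take, 1L, function(r) module_codes[[m]][r]),
                       use.names = FALSE)
    rec_pid <- c(rec_pid, pid[add_pat])
    rec_idx <- c(rec_idx, add_pat)
    drug <- c(drug, add_code)
  }

  ndays <- as.integer(cfg$window_end - cfg$window_start) + 1L
  date <- cfg$window_start +
    floor(stats::runif(length(rec_pid)) * ndays)

  records <- data.frame(
    patient_id = rec_pid,
    sex = sex[rec_idx],
    birth_year = birth_year[rec_idx],
    date = date,
    atc5 = drug,
    stringsAsFactors = FALSE
  )
  ord <- order(records$patient_id, records$date, records$atc5)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  list(records = records, catalog = catalog, modules = module_codes)
}

#' Write synthetic records as CSV
#'
#' Emits the dialect [loadRecords] reads by default (header
#' `patient_id,sex,birth_year,date,atc5`, ISO dates).
#'
#' @param records record data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRecordsCSV <- function(records, path) {
  out <- records
  out$date <- format(as.Date(out$date), "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
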