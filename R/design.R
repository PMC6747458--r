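#' Define one study group
#'
#' A group is one eye-condition of a cohort of animals: either the single
#' studied eye of an unlasered cohort, or the OHT or contralateral eye of
#' a unilaterally lasered cohort. OHT/contralateral groups sharing a
#' `cohort` label are generated from the same animals, which is what makes
#' the paired signed-rank comparisons meaningful.
#'
#' @param name group label (e.g. `"LG3d OHT"`).
#' @param cohort cohort label shared by paired eye groups.
#' @param eye_role `"single"`, `"OHT"` or `"contralateral"`.
#' @param profile an [activation_profile()].
#' @param n_animals number of animals (>= 2).
#' @param arm which quantification arm the cohort belongs to:
#'   `"microglia"`, `"rgc"` or `"both"`.
#' @param day analysis day (3 or 7), used to match treated against
#'   untreated cohorts; `NA` for unlasered groups.
#' @param saffron,lasered logical treatment flags.
#' @return a `rq_group` list.
#' @export
study_group <- function(name, cohort = name,
                        eye_role = c("single", "OHT", "contralateral"),
                        profile = profile_baseline(), n_animals = 6,
                        arm = c("microglia", "rgc", "both"),
                        day = NA_integer_, saffron = FALSE,
                        lasered = FALSE) {
  eye_role <- match.arg(eye_role)
  arm <- match.arg(arm)
  if (n_animals < 2) stop("`n_animals` must be at least 2")
  structure(list(name = name, cohort = cohort, eye_role = eye_role,
                 profile = profile, n_animals = as.integer(n_animals),
                 arm = arm, day = day, saffron = saffron,
                 lasered = lasered),
            class = "rq_group")
}

#' Define a synthetic study
#'
#' Bundles the group structure, field geometry and generator settings of
#' one synthetic experiment. Every lasered cohort must contribute a
#' matched OHT/contralateral pair of groups.
#'
#' @param groups list of [study_group()]s.
#' @param fields_per_retina fields generated per eye, distributed
#'   round-robin over the four zones.
#' @param geometry a [field_geometry()].
#' @param n_sections sections per z-stack for plexiform-layer images
#'   (1 generates plain 2-D fields).
#' @param noise_level,background generator noise settings.
#' @param base_counts named list of baseline planted counts per field for
#'   each layer class.
#' @param microglia_layers which of the microglia-arm image classes to
#'   generate (any of `"OS"`, `"OPL"`, `"IPL"`, `"NFL-GCL"`, `"OPL-OS"`);
#'   reduced sets speed up screening runs.
#' @param animal_sd SD of the per-animal log-normal density multiplier
#'   (shared by both eyes of an animal).
#' @param morpho_max_cells cells measured per field for soma/arbor
#'   morphometry.
#' @param seed integer master seed; every random draw in the study is a
#'   deterministic function of it.
#' @return an `rq_design` list.
#' @export
study_design <- function(groups, fields_per_retina = 8,
                         geometry = field_geometry(px = 256),
                         n_sections = 5, noise_level = 0.01,
                         background = 0.05,
                         base_counts = list(OS = 10, OPL = 16, IPL = 18,
                                            NFLGCL = 12, spots = 10,
                                            rgc = 120),
                         animal_sd = 0.06, morpho_max_cells = 4,
                         microglia_layers = c("OS", "OPL", "IPL",
                                              "NFL-GCL", "OPL-OS"),
                         seed = 1) {
  microglia_layers <- match.arg(microglia_layers, several.ok = TRUE)
  stopifnot(length(groups) >= 1)
  for (g in groups) stopifnot(inherits(g, "rq_group"))
  roles <- split(vapply(groups, function(g) g$eye_role, character(1)),
                 vapply(groups, function(g) g$cohort, character(1)))
  for (cohort in names(roles)) {
    r <- roles[[cohort]]
    if ("OHT" %in% r && !"contralateral" %in% r)
      stop("cohort ", cohort, " has an OHT group without its paired ",
           "contralateral group")
  }
  names(groups) <- vapply(groups, function(g) g$name, character(1))
  structure(list(groups = groups, fields_per_retina = fields_per_retina,
                 geometry = geometry, n_sections = n_sections,
                 noise_level = noise_level, background = background,
                 base_counts = base_counts, animal_sd = animal_sd,
                 morpho_max_cells = morpho_max_cells,
                 microglia_layers = microglia_layers,
                 seed = as.integer(seed)),
            class = "rq_design")
}

#' The emulated study's full group structure
#'
#' Builds the design with the cohort structure of the emulated
#' experiment: a naive control (n = 6), a saffron control (n = 8),
#' lasered and saffron + lasered cohorts analyzed at day 3 for the
#' microglia arm (n = 8 each, paired OHT/contralateral eyes) and at day 7
#' for the RGC arm (n = 6 each). Activation magnitudes come from the
#' illustrative [profile_oht()] family. At the default
#' `fields_per_retina = 8` the run is desk-scale: the original protocol
#' evaluated about 550 fields per retina, which remains reachable through
#' this argument.
#'
#' @inheritParams study_design
#' @param ... passed on to [study_design()].
#' @return an `rq_design`.
#' @export
paper_design <- function(fields_per_retina = 8, seed = 1, ...) {
  groups <- list(
    study_group("NG", eye_role = "single", n_animals = 6, arm = "both"),
    study_group("SCG", eye_role = "single", n_animals = 8, arm = "both",
                saffron = TRUE),
    study_group("LG3d OHT", cohort = "LG3d", eye_role = "OHT",
                profile = profile_oht(), n_animals = 8,
                arm = "microglia", day = 3, lasered = TRUE),
    study_group("LG3d contralateral", cohort = "LG3d",
                eye_role = "contralateral",
                profile = profile_oht_contralateral(), n_animals = 8,
                arm = "microglia", day = 3, lasered = TRUE),
    study_group("SLG3d OHT", cohort = "SLG3d", eye_role = "OHT",
                profile = profile_saffron_oht(), n_animals = 8,
                arm = "microglia", day = 3, saffron = TRUE,
                lasered = TRUE),
    study_group("SLG3d contralateral", cohort = "SLG3d",
                eye_role = "contralateral",
                profile = profile_saffron_contralateral(), n_animals = 8,
                arm = "microglia", day = 3, saffron = TRUE,
                lasered = TRUE),
    study_group("LG7d OHT", cohort = "LG7d", eye_role = "OHT",
                profile = profile_oht(), n_animals = 6, arm = "rgc",
                day = 7, lasered = TRUE),
    study_group("LG7d contralateral", cohort = "LG7d",
                eye_role = "contralateral",
                profile = profile_oht_contralateral(), n_animals = 6,
                arm = "rgc", day = 7, lasered = TRUE),
    study_group("SLG7d OHT", cohort = "SLG7d", eye_role = "OHT",
                profile = profile_saffron_oht(), n_animals = 6,
                arm = "rgc", day = 7, saffron = TRUE, lasered = TRUE),
    study_group("SLG7d contralateral", cohort = "SLG7d",
                eye_role = "contralateral",
                profile = profile_saffron_contralateral(), n_animals = 6,
                arm = "rgc", day = 7, saffron = TRUE, lasered = TRUE)
  )
  study_design(groups, fields_per_retina = fields_per_retina,
               seed = seed, ...)
}

#' Reduced design for fast end-to-end direction checks
#'
#' A minimal three-arm contrast (naive, OHT, saffron + OHT, plus the
#' day-7 RGC cohorts) at small image and sample sizes, used to check that
#' the full image -> detection -> morphometry -> statistics chain
#' reproduces the planted effect directions quickly.
#'
#' @inheritParams study_design
#' @export
pattern_design <- function(seed = 1, n_animals = 4,
                           fields_per_retina = 4,
                           geometry = field_geometry(px = 256)) {
  groups <- list(
    study_group("NG", eye_role = "single", n_animals = n_animals,
                arm = "both"),
    study_group("LG3d OHT", eye_role = "single",
                profile = profile_oht(), n_animals = n_animals,
                arm = "microglia", day = 3, lasered = TRUE),
    study_group("SLG3d OHT", eye_role = "single",
                profile = profile_saffron_oht(), n_animals = n_animals,
                arm = "microglia", day = 3, saffron = TRUE,
                lasered = TRUE),
    study_group("LG7d OHT", eye_role = "single",
                profile = profile_oht(), n_animals = n_animals,
                arm = "rgc", day = 7, lasered = TRUE),
    study_group("SLG7d OHT", eye_role = "single",
                profile = profile_saffron_oht(), n_animals = n_animals,
                arm = "rgc", day = 7, saffron = TRUE, lasered = TRUE)
  )
  study_design(groups, fields_per_retina = fields_per_retina,
               geometry = geometry, n_sections = 1,
               microglia_layers = c("OPL", "NFL-GCL"), seed = seed)
}

#' Read or write a study design as YAML
#'
#' @param design an `rq_design`.
#' @param path YAML file path.
#' @return `design_to_yaml()` returns `path` invisibly;
#'   `design_from_yaml()` returns the reconstructed `rq_design`.
#' @export
design_to_yaml <- function(design, path) {
  x <- list(
    seed = design$seed,
    fields_per_retina = design$fields_per_retina,
    px = design$geometry$px,
    area_mm2 = design$geometry$px^2 * design$geometry$pixel_size^2 / 1e6,
    n_sections = design$n_sections,
    noise_level = design$noise_level,
    background = design$background,
    animal_sd = design$animal_sd,
    morpho_max_cells = design$morpho_max_cells,
    microglia_layers = design$microglia_layers,
    base_counts = design$base_counts,
    groups = lapply(unname(design$groups), function(g) {
      list(name = g$name, cohort = g$cohort, eye_role = g$eye_role,
           n_animals = g$n_animals, arm = g$arm, day = g$day,
           saffron = g$saffron, lasered = g$lasered,
           profile = unclass(g$profile))
    })
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname design_to_yaml
#' @export
design_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  required <- c("seed", "groups")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0)
    stop("study config is missing fields: ", paste(missing, collapse = ", "))
  groups <- lapply(x$groups, function(g) {
    pr <- do.call(activation_profile, as.list(g$profile))
    study_group(g$name, cohort = g$cohort, eye_role = g$eye_role,
                profile = pr, n_animals = g$n_animals, arm = g$arm,
                day = if (is.null(g$day)) NA_integer_ else g$day,
                saffron = isTRUE(g$saffron), lasered = isTRUE(g$lasered))
  })
  study_design(
    groups,
    fields_per_retina = x$fields_per_retina %||% 8,
    geometry = field_geometry(px = x$px %||% 256,
                              area_mm2 = x$area_mm2 %||% 0.1502),
    n_sections = x$n_sections %||% 5,
    noise_level = x$noise_level %||% 0.01,
    background = x$background %||% 0.05,
    base_counts = x$base_counts %||% list(OS = 10, OPL = 16, IPL = 18,
                                          NFLGCL = 12, spots = 10,
                                          rgc = 120),
    animal_sd = x$animal_sd %||% 0.06,
    morpho_max_cells = x$morpho_max_cells %||% 4,
    microglia_layers = x$microglia_layers %||% c("OS", "OPL", "IPL",
                                                 "NFL-GCL", "OPL-OS"),
    seed = x$seed
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
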