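# ---- study orchestration: generate, quantify, aggregate, compare ----

# enumerate every image of the study as a plan row
.study_plan <- function(design) {
  zones <- rq_zones()
  rows <- list()
  for (g in design$groups) {
    arms <- if (g$arm == "both") c("microglia", "rgc") else g$arm
    for (animal in seq_len(g$n_animals)) {
      for (fi in seq_len(design$fields_per_retina)) {
        zone <- zones[((fi - 1) %% length(zones)) + 1]
        if ("microglia" %in% arms) {
          for (layer in design$microglia_layers) {
            rows[[length(rows) + 1]] <- list(
              group = g$name, cohort = g$cohort, eye_role = g$eye_role,
              animal = animal, zone = zone, field = fi, layer = layer,
              kind = if (layer == "OPL-OS") "vertical_spot" else "microglia")
          }
        }
        if ("rgc" %in% arms) {
          rows[[length(rows) + 1]] <- list(
            group = g$name, cohort = g$cohort, eye_role = g$eye_role,
            animal = animal, zone = zone, field = fi, layer = "NFL-GCL",
            kind = "rgc_nucleus")
        }
      }
    }
  }
  rows
}

# per-animal log-normal density multiplier, shared by both eyes
.animal_multiplier <- function(design, cohort, animal) {
  with_seed(derive_seed(design$seed, "animal", cohort, animal),
            exp(stats::rnorm(1, 0, design$animal_sd)))
}

# planted count for one plan row
.planted_n <- function(design, row, profile) {
  base <- switch(row$kind,
    microglia = switch(row$layer, OS = design$base_counts$OS,
                       OPL = design$base_counts$OPL,
                       IPL = design$base_counts$IPL,
                       `NFL-GCL` = design$base_counts$NFLGCL),
    vertical_spot = design$base_counts$spots,
    rgc_nucleus = design$base_counts$rgc)
  factor <- switch(row$kind,
    microglia = profile$density,
    vertical_spot = profile$spots,
    rgc_nucleus = profile$rgc_survival *
      (if (row$zone == "superior") profile$superior_rgc else 1))
  mult <- .animal_multiplier(design, row$cohort, row$animal)
  jitter <- with_seed(
    derive_seed(design$seed, "n", row$group, row$animal, row$zone,
                row$field, row$layer, row$kind),
    stats::runif(1, 0.92, 1.08))
  max(0L, as.integer(round(base * factor * mult * jitter)))
}

# realize one plan row as (image, truth); image may be a z-stack
.realize_row <- function(design, row) {
  g <- design$groups[[row$group]]
  n <- .planted_n(design, row, g$profile)
  seed <- derive_seed(design$seed, "img", row$group, row$animal,
                      row$zone, row$field, row$layer, row$kind)
  gen <- if (row$kind == "vertical_spot") {
    generate_vertical_spots(n, zone = row$zone,
                            geometry = design$geometry,
                            noise_level = design$noise_level,
                            background = design$background, seed = seed)
  } else {
    generate_layer_field(n, profile = g$profile, layer = row$layer,
                         zone = row$zone,
                         kind = if (row$kind == "rgc_nucleus")
                           "rgc_nucleus" else "microglia",
                         geometry = design$geometry,
                         noise_level = design$noise_level,
                         background = design$background, seed = seed)
  }
  if (design$n_sections > 1 && row$layer %in% c("OPL", "IPL") &&
      row$kind == "microglia") {
    gen <- as_zstack(gen, n_sections = design$n_sections,
                     noise_level = design$noise_level,
                     background = design$background,
                     seed = derive_seed(design$seed, "stack", row$group,
                                        row$animal, row$zone, row$field,
                                        row$layer))
  }
  gen$n_planted <- n
  gen
}

#' Generate a synthetic study to disk
#'
#' Writes every field of the design as a 16-bit TIFF (multi-page for
#' plexiform-layer z-stacks) under
#' `out_dir/<group>/animal_<i>/<zone>_f<k>_<layer>.tif`, together with a
#' master cell-level ground-truth CSV and the design as YAML. The output
#' is a pure function of the design (including its seed): two runs with
#' the same design produce byte-identical CSVs.
#'
#' @param design an `rq_design`.
#' @param out_dir output directory; must be empty unless
#'   `overwrite = TRUE`.
#' @param overwrite allow writing into a non-empty directory.
#' @return path to the ground-truth CSV, invisibly.
#' @export
generate_study <- function(design, out_dir, overwrite = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite)
    stop("output directory is not empty (use overwrite = TRUE): ", out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  plan <- .study_plan(design)
  truth_rows <- vector("list", length(plan))
  for (i in seq_along(plan)) {
    row <- plan[[i]]
    gen <- .realize_row(design, row)
    sub <- file.path(out_dir, gsub(" ", "_", row$group),
                     sprintf("animal_%02d", row$animal))
    dir.create(sub, showWarnings = FALSE, recursive = TRUE)
    fname <- sprintf("%s_f%02d_%s.tif", row$zone, row$field,
                     gsub("-", "", row$layer))
    write_field(gen$field, file.path(sub, fname))
    tr <- gen$truth
    if (nrow(tr) > 0) {
      meta <- data.frame(group = row$group, animal = row$animal,
                         eye = row$eye_role, layer = row$layer,
                         zone = row$zone, field = row$field,
                         stringsAsFactors = FALSE)
      truth_rows[[i]] <- cbind(meta[rep(1, nrow(tr)), , drop = FALSE], tr)
    }
  }
  truth <- do.call(rbind, truth_rows[!vapply(truth_rows, is.null,
                                             logical(1))])
  rownames(truth) <- NULL
  csv <- file.path(out_dir, "groundtruth.csv")
  utils::write.csv(truth, csv, row.names = FALSE)
  design_to_yaml(design, file.path(out_dir, "design.yaml"))
  invisible(csv)
}

# quantify one realized row into metric rows (long format)
.quantify_row <- function(design, row, gen, microglia_par, rgc_par,
                          spot_par) {
  meta <- data.frame(group = row$group, cohort = row$cohort,
                     eye_role = row$eye_role, animal = row$animal,
                     zone = row$zone, field = row$field,
                     layer = row$layer, stringsAsFactors = FALSE)
  out <- list()
  add <- function(metric, value) {
    out[[length(out) + 1]] <<- cbind(
      meta, data.frame(metric = metric, value = value,
                       n_planted = gen$n_planted))
  }
  if (row$kind == "vertical_spot") {
    det <- count_spots(project(gen$field, "mean"), spot_par)
    add("vertical_spots", det$count)
  } else if (row$kind == "rgc_nucleus") {
    det <- count_cells(gen$field, rgc_par)
    add("rgc_count", det$count)
  } else {
    fld <- project(gen$field, microglia_par$projection)
    det <- count_cells(fld, microglia_par)
    if (row$layer %in% c("OS", "OPL", "IPL")) add("iba1_count", det$count)
    if (row$layer == "NFL-GCL")
      add("iba1_ra", area_fraction(fld)$percent_area)
    if (row$layer %in% c("OPL", "IPL", "NFL-GCL") && det$count > 0) {
      mm <- measure_cells(fld, det, max_cells = design$morpho_max_cells)
      add("soma_area", mean(mm$soma_area_um2))
      if (row$layer != "NFL-GCL")
        add("arbor_area", mean(mm$arbor_area_um2))
    }
  }
  do.call(rbind, out)
}

#' Run the full synthetic study pipeline
#'
#' Generates every field of the design in memory (or reuses the design's
#' deterministic generator), quantifies each with the counting,
#' percent-area and morphometry measures appropriate to its layer,
#' aggregates per animal, and produces group summaries, the
#' unpaired/paired comparison grid and the zone-wise ANOVAs. The whole
#' run is a deterministic function of the design seed.
#'
#' @param design an `rq_design`, or a path to a YAML design file.
#' @param microglia_par,rgc_par,spot_par detection parameter sets for the
#'   three cell classes.
#' @param out_dir optional directory: when given, the result tables and a
#'   human-readable `report.md` are written there via [write_report()].
#' @return an `rq_report`: list with `per_field`, `per_animal`,
#'   `per_animal_zone`, `summaries`, `comparisons`, `zone_anova`,
#'   `provenance`.
#' @export
run_study <- function(design,
                      microglia_par = detection_params(),
                      rgc_par = rgc_params(),
                      spot_par = spot_params(),
                      out_dir = NULL) {
  if (is.character(design)) design <- design_from_yaml(design)
  stopifnot(inherits(design, "rq_design"))
  plan <- .study_plan(design)
  pf <- vector("list", length(plan))
  for (i in seq_along(plan)) {
    row <- plan[[i]]
    gen <- .realize_row(design, row)
    pf[[i]] <- .quantify_row(design, row, gen, microglia_par, rgc_par,
                             spot_par)
  }
  per_field <- do.call(rbind, pf[!vapply(pf, is.null, logical(1))])
  rownames(per_field) <- NULL
  per_animal <- aggregate_fields(per_field, level = "animal")
  per_animal_zone <- aggregate_fields(per_field, level = "animal_zone")
  summaries <- .group_summaries(per_animal)
  comparisons <- .comparison_grid(design, per_animal)
  zone_anova <- .zone_anova(design, per_animal_zone)
  report <- structure(
    list(design = design, per_field = per_field, per_animal = per_animal,
         per_animal_zone = per_animal_zone, summaries = summaries,
         comparisons = comparisons, zone_anova = zone_anova,
         provenance = list(
           seed = design$seed,
           design_hash = .design_hash(design),
           package_version = as.character(utils::packageVersion("retinaquant")))),
    class = "rq_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

.design_hash <- function(design) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  design_to_yaml(design, tmp)
  txt <- paste(readLines(tmp), collapse = "\n")
  h <- 0
  for (ch in utf8ToInt(txt)) h <- (h * 131 + ch) %% 2147483629
  sprintf("%08x", as.integer(h))
}

#' Aggregate per-field metrics
#'
#' Per-animal aggregation takes the mean over every field of one animal's
#' eye, per layer and metric (the study's default unit of analysis);
#' `"animal_zone"` keeps zones separate for the zone-wise ANOVAs;
#' `"field"` is a validated passthrough.
#'
#' @param per_field long-format data frame from [run_study()] (columns
#'   `group`, `cohort`, `eye_role`, `animal`, `zone`, `field`, `layer`,
#'   `metric`, `value`).
#' @param level `"animal"`, `"animal_zone"` or `"field"`.
#' @param required_layers optional layers that must be present; an error
#'   is raised if any is missing.
#' @return aggregated data frame.
#' @export
aggregate_fields <- function(per_field,
                             level = c("animal", "animal_zone", "field"),
                             required_layers = NULL) {
  level <- match.arg(level)
  needed <- c("group", "cohort", "eye_role", "animal", "zone", "field",
              "layer", "metric", "value")
  missing <- setdiff(needed, names(per_field))
  if (length(missing) > 0)
    stop("per-field table is missing columns: ",
         paste(missing, collapse = ", "))
  if (!is.null(required_layers)) {
    absent <- setdiff(required_layers, unique(per_field$layer))
    if (length(absent) > 0)
      stop("no fields for required layer(s): ",
           paste(absent, collapse = ", "))
  }
  if (level == "field") return(per_field)
  keys <- c("group", "cohort", "eye_role", "animal", "layer", "metric")
  if (level == "animal_zone") keys <- c(keys, "zone")
  agg <- stats::aggregate(per_field["value"], per_field[keys], mean)
  agg[do.call(order, agg[keys]), , drop = FALSE]
}

.group_summaries <- function(per_animal) {
  combos <- unique(per_animal[c("group", "layer", "metric")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- per_animal$group == combos$group[i] &
      per_animal$layer == combos$layer[i] &
      per_animal$metric == combos$metric[i]
    s <- summarize_metric(per_animal$value[sel], group = combos$group[i],
                          metric = combos$metric[i])
    s$layer <- combos$layer[i]
    s
  })
  out <- do.call(rbind, rows)
  out[order(out$metric, out$layer, out$group), ]
}

# comparison pairs implied by the group structure
.comparison_pairs <- function(design) {
  gs <- design$groups
  info <- data.frame(
    name = vapply(gs, `[[`, character(1), "name"),
    cohort = vapply(gs, `[[`, character(1), "cohort"),
    eye_role = vapply(gs, `[[`, character(1), "eye_role"),
    day = vapply(gs, function(g) as.integer(g$day %||% NA_integer_),
                 integer(1)),
    saffron = vapply(gs, `[[`, logical(1), "saffron"),
    lasered = vapply(gs, `[[`, logical(1), "lasered"),
    stringsAsFactors = FALSE)
  pairs <- list()
  add <- function(g1, g2, type) {
    pairs[[length(pairs) + 1]] <<- data.frame(group1 = g1, group2 = g2,
                                              type = type,
                                              stringsAsFactors = FALSE)
  }
  naive <- info$name[info$eye_role == "single" & !info$saffron & !info$lasered]
  scg <- info$name[info$eye_role == "single" & info$saffron & !info$lasered]
  if (length(naive) == 1 && length(scg) == 1)
    add(naive, scg, "unpaired")
  oht <- info[info$lasered & info$eye_role != "contralateral", , drop = FALSE]
  contra <- info[info$eye_role == "contralateral", , drop = FALSE]
  if (length(naive) == 1)
    for (g in oht$name) add(naive, g, "unpaired")
  for (d in unique(oht$day[!is.na(oht$day)])) {
    u <- oht$name[oht$day == d & !oht$saffron]
    t <- oht$name[oht$day == d & oht$saffron]
    if (length(u) == 1 && length(t) == 1) add(u, t, "unpaired")
    uc <- contra$name[contra$day == d & !contra$saffron]
    tc <- contra$name[contra$day == d & contra$saffron]
    if (length(uc) == 1 && length(tc) == 1) add(uc, tc, "unpaired")
  }
  for (co in unique(oht$cohort)) {
    g1 <- oht$name[oht$cohort == co]
    g2 <- contra$name[contra$cohort == co]
    if (length(g1) == 1 && length(g2) == 1) add(g1, g2, "paired")
  }
  do.call(rbind, pairs)
}

.comparison_grid <- function(design, per_animal) {
  pairs <- .comparison_pairs(design)
  combos <- unique(per_animal[c("metric", "layer")])
  rows <- list()
  for (p in seq_len(nrow(pairs))) {
    for (ci in seq_len(nrow(combos))) {
      sel1 <- per_animal$group == pairs$group1[p] &
        per_animal$metric == combos$metric[ci] &
        per_animal$layer == combos$layer[ci]
      sel2 <- per_animal$group == pairs$group2[p] &
        per_animal$metric == combos$metric[ci] &
        per_animal$layer == combos$layer[ci]
      if (!any(sel1) || !any(sel2)) next
      x1 <- per_animal[sel1, ]; x2 <- per_animal[sel2, ]
      if (pairs$type[p] == "paired") {
        common <- intersect(x1$animal, x2$animal)
        v1 <- x1$value[match(common, x1$animal)]
        v2 <- x2$value[match(common, x2$animal)]
        tst <- tryCatch(wilcoxon_signed_rank(v1, v2),
                        error = function(e) NULL)
      } else {
        v1 <- x1$value; v2 <- x2$value
        tst <- tryCatch(mann_whitney_u(v1, v2), error = function(e) NULL)
      }
      if (is.null(tst)) next
      rows[[length(rows) + 1]] <- data.frame(
        metric = combos$metric[ci], layer = combos$layer[ci],
        group1 = pairs$group1[p], group2 = pairs$group2[p],
        type = pairs$type[p], test = tst$test_name,
        statistic = tst$statistic, p_value = tst$p_value,
        method = tst$method,
        n1 = length(v1), n2 = length(v2),
        mean1 = mean(v1), sd1 = stats::sd(v1),
        mean2 = mean(v2), sd2 = stats::sd(v2),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.zone_anova <- function(design, per_animal_zone) {
  targets <- rbind(
    data.frame(metric = "iba1_count", layer = c("OS", "OPL", "IPL")),
    data.frame(metric = "iba1_ra", layer = "NFL-GCL"),
    data.frame(metric = "rgc_count", layer = "NFL-GCL"))
  oht_groups <- names(Filter(function(g)
    g$lasered && g$eye_role != "contralateral", design$groups))
  rows <- list()
  for (g in oht_groups) {
    for (ti in seq_len(nrow(targets))) {
      sel <- per_animal_zone$group == g &
        per_animal_zone$metric == targets$metric[ti] &
        per_animal_zone$layer == targets$layer[ti]
      if (sum(sel) < 8) next
      d <- per_animal_zone[sel, ]
      tst <- tryCatch(anova_bonferroni(d$value, d$zone),
                      error = function(e) NULL)
      if (is.null(tst)) next
      rows[[length(rows) + 1]] <- data.frame(
        group = g, metric = targets$metric[ti],
        layer = targets$layer[ti], f_statistic = tst$statistic,
        p_value = tst$p_value,
        min_adjusted_pairwise_p = min(tst$pairwise$adjusted_p),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) rownames(out) <- NULL
  out
}

#' Write a study report to disk
#'
#' Writes `per_field.csv`, `per_animal.csv`, `comparisons.csv`,
#' `zone_anova.csv`, `summaries.csv` and a human-readable `report.md`
#' with provenance (seed, design hash, package version).
#'
#' @param report an `rq_report` from [run_study()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "rq_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$per_field, file.path(out_dir, "per_field.csv"),
                   row.names = FALSE)
  utils::write.csv(report$per_animal,
                   file.path(out_dir, "per_animal.csv"),
                   row.names = FALSE)
  utils::write.csv(report$summaries, file.path(out_dir, "summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(report$comparisons,
                   file.path(out_dir, "comparisons.csv"),
                   row.names = FALSE)
  if (!is.null(report$zone_anova))
    utils::write.csv(report$zone_anova,
                     file.path(out_dir, "zone_anova.csv"),
                     row.names = FALSE)
  md <- c(
    "# Synthetic retinal quantification report",
    "",
    sprintf("- seed: %d", report$provenance$seed),
    sprintf("- design hash: %s", report$provenance$design_hash),
    sprintf("- package version: %s", report$provenance$package_version),
    sprintf("- groups: %s", paste(names(report$design$groups),
                                  collapse = ", ")),
    sprintf("- fields per retina: %d (desk-scale; the emulated protocol used ~550 per retina)",
            report$design$fields_per_retina),
    "",
    "## Group summaries (mean ± SD, per-animal unit)",
    "",
    "| metric | layer | group | n | mean | sd |",
    "|---|---|---|---|---|---|",
    sprintf("| %s | %s | %s | %d | %.3f | %.3f |",
            report$summaries$metric, report$summaries$layer,
            report$summaries$group, report$summaries$n,
            report$summaries$mean, report$summaries$sd),
    "",
    "## Comparisons",
    "",
    "| metric | layer | comparison | test | p |",
    "|---|---|---|---|---|",
    sprintf("| %s | %s | %s vs %s | %s | %.4g |",
            report$comparisons$metric, report$comparisons$layer,
            report$comparisons$group1, report$comparisons$group2,
            report$comparisons$test, report$comparisons$p_value))
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(out_dir)
}

#' Check the planted effect-direction pattern of a report
#'
#' Evaluates, from the group summaries of a completed run, whether the
#' pipeline reproduced the qualitative activation pattern planted by the
#' OHT and saffron profiles: microglial number, soma area and percent
#' area higher under OHT than naive; arbor area lower; the saffron-OHT
#' group attenuated toward naive on each of those; RGC count lower under
#' OHT and recovering to near-naive with saffron (above the untreated
#' OHT group and deviating from naive by less than the OHT deficit).
#'
#' @param report an `rq_report` containing `"NG"`, an untreated OHT group
#'   and a saffron OHT group for both arms.
#' @return named logical vector of direction checks, with attribute
#'   `all_pass`.
#' @export
pattern_check <- function(report) {
  s <- report$summaries
  gmean <- function(group, metric, layer) {
    v <- s$mean[s$group == group & s$metric == metric & s$layer == layer]
    if (length(v) != 1) NA_real_ else v
  }
  grp <- names(report$design$groups)
  is_oht <- function(g) g$lasered && g$eye_role != "contralateral"
  oht3 <- grp[vapply(report$design$groups, function(g)
    is_oht(g) && !g$saffron && g$arm != "rgc", logical(1))][1]
  slg3 <- grp[vapply(report$design$groups, function(g)
    is_oht(g) && g$saffron && g$arm != "rgc", logical(1))][1]
  oht7 <- grp[vapply(report$design$groups, function(g)
    is_oht(g) && !g$saffron && g$arm == "rgc", logical(1))][1]
  slg7 <- grp[vapply(report$design$groups, function(g)
    is_oht(g) && g$saffron && g$arm == "rgc", logical(1))][1]
  checks <- c()
  dir_up <- function(metric, layer, nm) {
    ng <- gmean("NG", metric, layer); lg <- gmean(oht3, metric, layer)
    sl <- gmean(slg3, metric, layer)
    checks[paste0(nm, "_oht_up")] <<- isTRUE(lg > ng)
    checks[paste0(nm, "_saffron_attenuated")] <<-
      isTRUE(abs(sl - ng) < abs(lg - ng))
  }
  dir_down <- function(metric, layer, nm) {
    ng <- gmean("NG", metric, layer); lg <- gmean(oht3, metric, layer)
    sl <- gmean(slg3, metric, layer)
    checks[paste0(nm, "_oht_down")] <<- isTRUE(lg < ng)
    checks[paste0(nm, "_saffron_attenuated")] <<-
      isTRUE(abs(sl - ng) < abs(lg - ng))
  }
  dir_up("iba1_count", "OPL", "count")
  dir_up("soma_area", "OPL", "soma")
  dir_up("iba1_ra", "NFL-GCL", "iba1_ra")
  dir_down("arbor_area", "OPL", "arbor")
  ng <- gmean("NG", "rgc_count", "NFL-GCL")
  lg <- gmean(oht7, "rgc_count", "NFL-GCL")
  sl <- gmean(slg7, "rgc_count", "NFL-GCL")
  checks["rgc_oht_down"] <- isTRUE(lg < ng)
  checks["rgc_saffron_near_naive"] <- isTRUE(sl > lg &&
                                               abs(sl - ng) < abs(lg - ng))
  attr(checks, "all_pass") <- all(checks)
  checks
}
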