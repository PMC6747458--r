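# a deliberately tiny paired design used across these tests
tiny_design <- function(seed = 1, layers = "OPL", fields = 2,
                        n_animals = 2, px = 128) {
  groups <- list(
    study_group("NG", eye_role = "single", n_animals = n_animals,
                arm = "microglia"),
    study_group("LG3d OHT", cohort = "LG3d", eye_role = "OHT",
                profile = profile_oht(), n_animals = n_animals,
                arm = "microglia", day = 3, lasered = TRUE),
    study_group("LG3d contralateral", cohort = "LG3d",
                eye_role = "contralateral",
                profile = profile_oht_contralateral(),
                n_animals = n_animals, arm = "microglia", day = 3,
                lasered = TRUE))
  study_design(groups, fields_per_retina = fields,
               geometry = field_geometry(px = px), n_sections = 1,
               microglia_layers = layers, seed = seed)
}

test_that("per-animal aggregation is the mean over an animal's fields", {
  pf <- data.frame(group = "NG", cohort = "NG", eye_role = "single",
                   animal = 1, zone = c("superior", "inferior", "nasal"),
                   field = 1:3, layer = "OPL", metric = "iba1_count",
                   value = c(10, 12, 14))
  agg <- aggregate_fields(pf, level = "animal")
  expect_equal(nrow(agg), 1)
  expect_equal(agg$value, 12)
  # passthrough keeps rows
  expect_equal(nrow(aggregate_fields(pf, level = "field")), 3)
  # missing required layer is an explicit error
  expect_error(aggregate_fields(pf, required_layers = c("OPL", "IPL")),
               "required layer")
  expect_error(aggregate_fields(pf[, -3], level = "animal"),
               "missing columns")
})

test_that("aggregation then summary equals the two-stage oracle", {
  set.seed(13)
  pf <- expand.grid(animal = 1:3, field = 1:4)
  pf <- data.frame(group = "NG", cohort = "NG", eye_role = "single",
                   animal = pf$animal, zone = "superior", field = pf$field,
                   layer = "OPL", metric = "iba1_count",
                   value = rpois(12, 15))
  agg <- aggregate_fields(pf, level = "animal")
  s <- summarize_metric(agg$value, "NG", "iba1_count")
  oracle_means <- tapply(pf$value, pf$animal, mean)
  expect_equal(s$mean, mean(oracle_means))
  expect_equal(s$sd, sd(oracle_means))
  expect_equal(s$n, 3)
})

test_that("designs require paired contralateral groups and round-trip YAML", {
  expect_error(
    study_design(list(
      study_group("L OHT", cohort = "L", eye_role = "OHT",
                  n_animals = 2, lasered = TRUE))),
    "paired")
  d <- tiny_design(seed = 42)
  tmp <- file.path(tempdir(), "design.yaml")
  design_to_yaml(d, tmp)
  d2 <- design_from_yaml(tmp)
  expect_equal(d2$seed, d$seed)
  expect_equal(names(d2$groups), names(d$groups))
  expect_equal(d2$groups[["LG3d OHT"]]$profile$density,
               profile_oht()$density)
  expect_equal(d2$geometry$pixel_size, d$geometry$pixel_size)
  expect_equal(d2$microglia_layers, d$microglia_layers)
  unlink(tmp)
})

test_that("generate_study writes a deterministic tree and refuses clobbering", {
  d <- tiny_design(seed = 7, fields = 1, n_animals = 2, px = 96)
  out1 <- file.path(tempdir(), "study1")
  out2 <- file.path(tempdir(), "study2")
  unlink(c(out1, out2), recursive = TRUE)
  generate_study(d, out1)
  generate_study(d, out2)
  csv1 <- readBin(file.path(out1, "groundtruth.csv"), "raw", 3e6)
  csv2 <- readBin(file.path(out2, "groundtruth.csv"), "raw", 3e6)
  expect_identical(csv1, csv2)
  # per-animal subtrees exist for every group
  expect_length(dir(file.path(out1, "NG")), 2)
  expect_true(file.exists(file.path(out1, "design.yaml")))
  # a non-empty output directory is refused without overwrite
  expect_error(generate_study(d, out1), "not empty")
  expect_silent(generate_study(d, out1, overwrite = TRUE))
  tr <- read.csv(file.path(out1, "groundtruth.csv"))
  expect_true(all(c("group", "animal", "eye", "layer", "zone", "field",
                    "kind", "x_um", "y_um", "soma_radius_um",
                    "n_processes", "tips_json", "peak") %in% names(tr)))
  unlink(c(out1, out2), recursive = TRUE)
})

test_that("planted density factor shows up in the ground-truth counts", {
  d <- tiny_design(seed = 19, fields = 4, n_animals = 3, px = 96)
  out <- file.path(tempdir(), "study_density")
  unlink(out, recursive = TRUE)
  generate_study(d, out)
  tr <- read.csv(file.path(out, "groundtruth.csv"))
  per_field <- aggregate(x_um ~ group + animal + zone + field, tr,
                         FUN = length)
  m <- tapply(per_field$x_um, per_field$group, mean)
  ratio <- m[["LG3d OHT"]] / m[["NG"]]
  expect_lt(abs(ratio - profile_oht()$density), 0.15 * 1.3)
  unlink(out, recursive = TRUE)
})

test_that("run_study produces the full comparison grid with pairing", {
  d <- tiny_design(seed = 3, fields = 2, n_animals = 3, px = 128)
  rep <- run_study(d)
  expect_s3_class(rep, "rq_report")
  # group sizes propagate into every summary
  expect_true(all(rep$summaries$n == 3))
  cmp <- rep$comparisons
  # NG vs OHT unpaired and OHT vs contralateral paired, for each metric
  expect_true(any(cmp$group1 == "NG" & cmp$group2 == "LG3d OHT" &
                  cmp$test == "mann_whitney_u"))
  paired <- cmp[cmp$type == "paired", ]
  expect_true(all(paired$test == "wilcoxon_signed_rank"))
  expect_true(any(paired$group1 == "LG3d OHT" &
                  paired$group2 == "LG3d contralateral"))
  # each configured comparison appears exactly once per metric/layer
  key <- paste(cmp$metric, cmp$layer, cmp$group1, cmp$group2)
  expect_equal(anyDuplicated(key), 0)
  # provenance is populated
  expect_equal(rep$provenance$seed, 3)
  expect_match(rep$provenance$design_hash, "^[0-9a-f]+$")
})

test_that("written reports are byte-stable across identical runs", {
  d <- tiny_design(seed = 23, fields = 1, n_animals = 2, px = 96)
  o1 <- file.path(tempdir(), "rep1"); o2 <- file.path(tempdir(), "rep2")
  unlink(c(o1, o2), recursive = TRUE)
  run_study(d, out_dir = o1)
  run_study(d, out_dir = o2)
  for (f in c("per_field.csv", "per_animal.csv", "comparisons.csv",
              "summaries.csv")) {
    expect_identical(readBin(file.path(o1, f), "raw", 3e6),
                     readBin(file.path(o2, f), "raw", 3e6),
                     info = f)
  }
  expect_true(file.exists(file.path(o1, "report.md")))
  unlink(c(o1, o2), recursive = TRUE)
})

test_that("zone ANOVA runs for OHT groups when zones are populated", {
  d <- tiny_design(seed = 29, fields = 8, n_animals = 3, px = 96)
  rep <- run_study(d)
  za <- rep$zone_anova
  expect_true(!is.null(za))
  expect_true(all(za$group == "LG3d OHT"))
  expect_true(all(za$p_value >= 0 & za$p_value <= 1))
})
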