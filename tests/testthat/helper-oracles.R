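# Independent oracles and fixtures shared across the test files.

# Linear-scan point lookup, written independently of the package's
# vectorised table lookup: walk the thresholds in order and count bands
# passed.
linear_scan_points <- function(value, thresholds, points, ge = FALSE) {
  k <- 0L
  for (th in thresholds) {
    passed <- if (ge) value >= th else value > th
    if (passed) k <- k + 1L else break
  }
  points[k + 1L]
}

# Componentwise score oracle: applies the table lookups and the
# conditional protein rule by hand, mirroring the transcribed rules.
oracle_score <- function(profile, category, tables = ns_tables()) {
  ct <- tables$categories[[category]]
  val <- function(cmp) switch(cmp,
    energy = profile$energy_kj, sugars = profile$sugars_g,
    saturated_fat = profile$satfat_g, salt = profile$salt_g,
    satfat_ratio = if (profile$totalfat_g > 0)
      100 * profile$satfat_g / profile$totalfat_g else NA_real_,
    fibre = profile$fibre_g, protein = profile$protein_g,
    fvl = profile$fvl_pct)
  pts <- function(cmp) {
    v <- val(cmp)
    if (is.na(v)) return(0L)  # fats ratio with zero total fat
    tb <- ct$components[[cmp]]
    linear_scan_points(v, tb$thresholds, tb$points,
                       ge = identical(tb$boundary, "ge"))
  }
  a <- sum(vapply(ct$unfavourable, pts, numeric(1)))
  rule <- tables$protein_rule
  fvl <- pts("fvl")
  protein <- pts("protein")
  if (category == "red_meat_product")
    protein <- min(protein, rule$red_meat_protein_cap)
  if (category %in% rule$applies_to && a >= rule$a_points_cutoff &&
      fvl < rule$fvl_full_points)
    protein <- 0
  c_ <- pts("fibre") + fvl + protein
  list(a = a, c = c_, score = a - c_)
}

random_profile <- function() {
  tf <- runif(1, 0, 60)
  nutrient_profile(
    energy_kj = runif(1, 0, 4000), sugars_g = runif(1, 0, 70),
    satfat_g = tf * runif(1), totalfat_g = tf,
    salt_g = runif(1, 0, 5), fibre_g = runif(1, 0, 12),
    protein_g = runif(1, 0, 30), fvl_pct = runif(1, 0, 100))
}

# worst- and best-case general-food profiles (beyond every threshold /
# at every favourable maximum)
worst_general_profile <- function() nutrient_profile(
  energy_kj = 5000, sugars_g = 80, satfat_g = 20, totalfat_g = 40,
  salt_g = 6, fibre_g = 0, protein_g = 0, fvl_pct = 0)

best_general_profile <- function() nutrient_profile(
  energy_kj = 100, sugars_g = 0, satfat_g = 0, totalfat_g = 0.5,
  salt_g = 0, fibre_g = 10, protein_g = 20, fvl_pct = 95)

# degenerate point tables: every component has a single 0-point band
degenerate_tables <- function() {
  comp <- list(thresholds = numeric(0), points = 0)
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    version = "degenerate",
    units = list(kj_per_kcal = 4.184, salt_per_sodium = 2.5),
    categories = list(general_food = list(
      unfavourable = list("energy", "sugars", "saturated_fat", "salt"),
      favourable = list("fibre", "protein", "fvl"),
      components = list(energy = comp, sugars = comp,
                        saturated_fat = comp, salt = comp, fibre = comp,
                        protein = comp, fvl = comp),
      letters = list(breaks = list(0), labels = list("A", "B")))),
    protein_rule = list(a_points_cutoff = 11, fvl_full_points = 5,
                        applies_to = list("general_food"),
                        red_meat_protein_cap = 2)), path)
  ns_tables(path)
}

# tiny item table for hand-arithmetic intake tests
toy_items <- function() {
  data.frame(item_id = c("bread", "oil", "wine"),
             portion_g = c(100, 10, 150),
             energy_kcal = c(200, 900, 70),
             protein_g = c(8, 0, 0), totalfat_g = c(2, 100, 0),
             carb_g = c(40, 0, 2), fibre_g = c(3, 0, 0),
             alcohol_g = c(0, 0, 10), stringsAsFactors = FALSE)
}
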