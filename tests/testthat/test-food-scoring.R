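test_that("component point lookups: below, between and above thresholds", {
  expect_identical(points_for_component("sugars", 0, "general_food"), 0L)
  # saturation just above the top threshold
  expect_identical(points_for_component("sugars", 51.01, "general_food"),
                   15L)
  # a value exactly at a threshold earns the lower band
  expect_identical(points_for_component("sugars", 3.4, "general_food"), 0L)
  expect_identical(points_for_component("energy", 1500, "general_food"),
                   4L)  # 1340 < 1500 <= 1675
  # beverages use their own (stricter) energy scale
  expect_identical(points_for_component("energy", 200, "beverage"), 3L)
  expect_error(points_for_component("fvl", -1, "general_food"), "negative")
  expect_error(points_for_component("sugars", 1, "no_such_cat"),
               "unknown category")
  expect_error(points_for_component("satfat_ratio", 1, "general_food"),
               "not defined")
})

test_that("unfavourable totals: zero, saturated, and componentwise sums", {
  zero <- nutrient_profile()
  expect_identical(compute_unfavourable_points(zero, "general_food"), 0L)
  expect_identical(
    compute_unfavourable_points(worst_general_profile(), "general_food"),
    55L)
  p <- nutrient_profile(energy_kj = 1500, sugars_g = 22, satfat_g = 4.5,
                        totalfat_g = 9, salt_g = 1.25)
  expect_equal(compute_unfavourable_points(p, "general_food"),
               oracle_score(p, "general_food")$a)
  # fats/oils: saturate ratio replaces absolute saturated fat
  oil <- nutrient_profile(energy_kj = 3700, satfat_g = 14, totalfat_g = 100)
  tab <- ns_tables()
  expect_identical(
    compute_unfavourable_points(oil, "fats_oils_nuts_seeds"),
    10L + 0L + points_for_component("satfat_ratio", 14,
                                    "fats_oils_nuts_seeds") + 0L)
  # ratio rule with zero total fat contributes zero points
  nofat <- nutrient_profile(energy_kj = 500)
  expect_identical(
    compute_unfavourable_points(nofat, "fats_oils_nuts_seeds"),
    points_for_component("energy", 500, "fats_oils_nuts_seeds"))
})

test_that("conditional protein rule: suppression, FVL exemption, cheese, red meat", {
  # protein-rich but unfavourable food: a_points >= 11 suppresses protein
  p <- nutrient_profile(energy_kj = 2500, sugars_g = 30, satfat_g = 6,
                        totalfat_g = 12, salt_g = 1, fibre_g = 4,
                        protein_g = 20, fvl_pct = 0)
  a <- compute_unfavourable_points(p, "general_food")
  expect_gte(a, 11)
  expect_identical(compute_favourable_points(p, "general_food", a),
                   points_for_component("fibre", 4, "general_food"))
  # same profile with full FVL keeps its protein points
  p_fvl <- nutrient_profile(energy_kj = 2500, sugars_g = 30, satfat_g = 6,
                            totalfat_g = 12, salt_g = 1, fibre_g = 4,
                            protein_g = 20, fvl_pct = 85)
  expect_identical(
    compute_favourable_points(p_fvl, "general_food", a),
    points_for_component("fibre", 4, "general_food") + 5L + 7L)
  # cheese always counts protein
  expect_identical(
    compute_favourable_points(p, "cheese", a),
    points_for_component("fibre", 4, "general_food") + 7L)
  # red meat: protein capped at 2 even when a_points is low
  lean <- nutrient_profile(energy_kj = 500, protein_g = 22)
  a2 <- compute_unfavourable_points(lean, "red_meat_product")
  expect_lt(a2, 11)
  expect_identical(compute_favourable_points(lean, "red_meat_product", a2),
                   2L)
  expect_identical(compute_favourable_points(lean, "general_food", a2), 7L)
})

test_that("compute_score agrees with the componentwise oracle on random profiles", {
  set.seed(421)
  cats <- c("general_food", "beverage", "fats_oils_nuts_seeds", "cheese",
            "red_meat_product")
  for (i in 1:200) {
    p <- random_profile()
    cat <- sample(cats, 1)
    fs <- compute_score(p, cat)
    or <- oracle_score(p, cat)
    expect_identical(fs$a_points, as.integer(or$a))
    expect_identical(fs$c_points, as.integer(or$c))
    expect_identical(fs$score, as.integer(or$score))
    expect_identical(fs$score, fs$a_points - fs$c_points)
  }
})

test_that("score is monotone in each nutrient direction", {
  set.seed(99)
  for (i in 1:40) {
    p <- random_profile()
    s0 <- compute_score(p, "general_food")$score
    worse <- p
    worse$sugars_g <- p$sugars_g + runif(1, 0, 20)
    worse$salt_g <- p$salt_g + runif(1, 0, 2)
    expect_gte(compute_score(worse, "general_food")$score, s0)
    better <- p
    better$fibre_g <- p$fibre_g + runif(1, 0, 5)
    better$fvl_pct <- min(100, p$fvl_pct + runif(1, 0, 30))
    expect_lte(compute_score(better, "general_food")$score, s0)
  }
})

test_that("letter classes are monotone with documented band boundaries", {
  # general foods: A <= 0 < B <= 2 < C <= 10 < D <= 18 < E
  expect_identical(classify_letter(c(-17, 0, 1, 2, 3, 10, 11, 18, 19, 55),
                                   "general_food"),
                   c("A", "A", "B", "B", "C", "C", "D", "D", "E", "E"))
  # fats/oils: A band extends to -6
  expect_identical(classify_letter(c(-7, -6, -5, 2, 3), "fats_oils_nuts_seeds"),
                   c("A", "A", "B", "B", "C"))
  # water is always A; other beverages can never reach A
  expect_identical(classify_letter(0, "water"), "A")
  rng <- score_extrema("beverage")
  lv <- unique(classify_letter(seq(rng[1], rng[2]), "beverage"))
  expect_identical(sort(lv), c("B", "C", "D", "E"))
  expect_error(classify_letter(100, "general_food"), "attainable range")
})

test_that("score extrema by exhaustive enumeration per category", {
  expect_identical(score_extrema("general_food"), c(-17L, 55L))
  expect_identical(score_extrema("fats_oils_nuts_seeds"), c(-17L, 55L))
  # beverage extrema from the transcribed beverage tables:
  # A side 10+10+10+20 = 50; C side 5+7+6 = 18 (no protein suppression)
  expect_identical(score_extrema("beverage"), c(-18L, 50L))
  expect_identical(score_extrema("water"), c(0L, 0L))
  expect_identical(score_extrema("general_food", degenerate_tables()),
                   c(0L, 0L))
})

test_that("profile validation errors name the offending field", {
  expect_error(nutrient_profile(sugars_g = -1), "sugars_g")
  expect_error(nutrient_profile(fvl_pct = 120), "fvl_pct")
  expect_error(nutrient_profile(satfat_g = 5, totalfat_g = 2),
               "exceeds total fat")
  expect_error(compute_score(list(energy_kj = -5), "general_food"),
               "energy_kj")
})

test_that("score_foods converts kcal and sodium at ingestion", {
  foods <- data.frame(item_id = c("a", "b"), category = "general_food",
                      energy_kcal = c(100, 480), sugars_g = 0,
                      satfat_g = 0, totalfat_g = 0, sodium_g = c(0, 0.4),
                      fibre_g = 0, protein_g = 0, fvl_pct = 0)
  sc <- score_foods(foods)
  # 100 kcal = 418.4 kJ -> 1 energy point; 480 kcal = 2008.3 kJ -> 5
  # 0.4 g sodium -> 1 g salt -> 4 salt points
  expect_identical(sc$a_points, c(1L, 9L))
  expect_identical(sc$score, sc$a_points - sc$c_points)
})
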