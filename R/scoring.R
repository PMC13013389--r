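#' Construct and validate a nutrient profile
#'
#' A nutrient profile holds the per-100 g (solid foods) or per-100 mL
#' (beverages) composition needed by the 2023 Nutri-Score algorithm:
#' energy, total sugars, saturated fat, total fat (for the fats/oils
#' saturates-to-total-fat ratio), salt, fibre, protein, and the percentage
#' of fruits, vegetables and legumes (FVL).
#'
#' @param energy_kj Energy in kJ per 100 g (or 100 mL).
#' @param sugars_g,satfat_g,totalfat_g,salt_g,fibre_g,protein_g Grams per
#'   100 g (or 100 mL).
#' @param fvl_pct Percentage of fruits, vegetables and legumes, in
#'   `[0, 100]`.
#' @return A list of class `nutrient_profile`.
#' @examples
#' nutrient_profile(energy_kj = 1500, sugars_g = 12, satfat_g = 3,
#'                  totalfat_g = 9, salt_g = 0.9, fibre_g = 2,
#'                  protein_g = 6, fvl_pct = 0)
#' @export
nutrient_profile <- function(energy_kj = 0, sugars_g = 0, satfat_g = 0,
                             totalfat_g = 0, salt_g = 0, fibre_g = 0,
                             protein_g = 0, fvl_pct = 0) {
  p <- list(energy_kj = energy_kj, sugars_g = sugars_g, satfat_g = satfat_g,
            totalfat_g = totalfat_g, salt_g = salt_g, fibre_g = fibre_g,
            protein_g = protein_g, fvl_pct = fvl_pct)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop("nutrient profile field '", nm, "' must be a single number")
    if (v < 0)
      stop("nutrient profile field '", nm, "' is negative (", v, ")")
  }
  if (p$fvl_pct > 100)
    stop("nutrient profile field 'fvl_pct' exceeds 100 (", p$fvl_pct, ")")
  if (p$totalfat_g > 0 && p$satfat_g > p$totalfat_g + 1e-9)
    stop("saturated fat (", p$satfat_g, " g) exceeds total fat (",
         p$totalfat_g, " g)")
  structure(p, class = "nutrient_profile")
}

.check_category <- function(category) {
  if (!is.character(category) || length(category) != 1L ||
      !category %in% NS_CATEGORIES)
    stop("unknown food category '", paste(category, collapse = ","),
         "'; expected one of: ", paste(NS_CATEGORIES, collapse = ", "))
  category
}

#' Unfavourable ("A") component points
#'
#' Sums the points of the four components to be limited: energy, sugars,
#' saturated fat and salt.  For the fats/oils/nuts/seeds category the
#' saturated-fat component is replaced by the ratio of saturates to total
#' fat (x 100); when total fat is zero the ratio component contributes 0
#' points by convention.
#'
#' @param profile A [nutrient_profile()].
#' @param category Food category.
#' @param tables Point tables from [ns_tables()].
#' @return Integer total in `[0, 55]` for solid-food categories.
#' @export
compute_unfavourable_points <- function(profile, category,
                                        tables = ns_tables()) {
  .check_category(category)
  comps <- tables$categories[[category]]$unfavourable
  total <- 0L
  for (cmp in comps) {
    value <- switch(cmp,
      energy = profile$energy_kj,
      sugars = profile$sugars_g,
      saturated_fat = profile$satfat_g,
      salt = profile$salt_g,
      satfat_ratio = if (profile$totalfat_g > 0)
        100 * profile$satfat_g / profile$totalfat_g else NA_real_,
      stop("unhandled unfavourable component '", cmp, "'"))
    if (cmp == "satfat_ratio" && is.na(value)) next  # total fat 0 -> 0 pts
    total <- total + points_for_component(cmp, value, category, tables)
  }
  total
}

#' Favourable ("C") component points with the conditional protein rule
#'
#' Sums fibre, FVL and protein points.  The protein component is
#' conditional: for categories subject to the rule, a food whose
#' unfavourable total reaches the cutoff (11 points in the 2023 model)
#' earns no protein points unless it holds the full FVL component; cheese
#' always counts protein; red meat and products thereof have protein
#' points capped (at 2 in the 2023 model).  All rule constants live in the
#' point-table file.
#'
#' @param profile A [nutrient_profile()].
#' @param category Food category.
#' @param a_points Unfavourable total, already computed (the rule is
#'   conditional on it).
#' @param tables Point tables from [ns_tables()].
#' @return Integer total in `[0, 17]` for solid-food categories.
#' @export
compute_favourable_points <- function(profile, category, a_points,
                                      tables = ns_tables()) {
  .check_category(category)
  rule <- tables$protein_rule
  fibre <- points_for_component("fibre", profile$fibre_g, category, tables)
  fvl <- points_for_component("fvl", profile$fvl_pct, category, tables)
  protein <- points_for_component("protein", profile$protein_g, category,
                                  tables)
  if (category == "red_meat_product")
    protein <- min(protein, as.integer(rule$red_meat_protein_cap))
  if (category %in% rule$applies_to &&
      a_points >= rule$a_points_cutoff &&
      fvl < rule$fvl_full_points)
    protein <- 0L
  fibre + fvl + protein
}

#' Compute the 2023 Nutri-Score of a food or beverage
#'
#' Final score = unfavourable points - favourable points (with the
#' conditional protein rule applied); for general foods it spans -17 to
#' +55, higher meaning poorer nutritional quality.  Plain water bypasses
#' the tables: best letter class, numeric score 0 (the value used when the
#' item enters a dietary index).
#'
#' @param profile A [nutrient_profile()] (ignored for `water`).
#' @param category Food category.
#' @param tables Point tables from [ns_tables()].
#' @return A list of class `food_score` with elements `a_points`,
#'   `c_points`, `score`, `letter` and `category`.
#' @examples
#' p <- nutrient_profile(energy_kj = 2000, sugars_g = 30, satfat_g = 8,
#'                       totalfat_g = 15, salt_g = 1.2)
#' compute_score(p, "general_food")
#' @export
compute_score <- function(profile, category, tables = ns_tables()) {
  .check_category(category)
  if (category == "water") {
    return(structure(list(a_points = 0L, c_points = 0L, score = 0L,
                          letter = "A", category = category),
                     class = "food_score"))
  }
  if (!inherits(profile, "nutrient_profile"))
    profile <- do.call(nutrient_profile, as.list(profile))
  a <- compute_unfavourable_points(profile, category, tables)
  c_ <- compute_favourable_points(profile, category, a, tables)
  score <- as.integer(a - c_)
  structure(list(a_points = as.integer(a), c_points = as.integer(c_),
                 score = score,
                 letter = classify_letter(score, category, tables),
                 category = category),
            class = "food_score")
}

#' @export
print.food_score <- function(x, ...) {
  cat(sprintf("Nutri-Score (%s): %+d  [A=%d, C=%d]  class %s\n",
              x$category, x$score, x$a_points, x$c_points, x$letter))
  invisible(x)
}

#' Letter class of a Nutri-Score
#'
#' Maps a numeric score to the five colour-coded letter classes A (best)
#' to E (worst).  Bands are category-specific and monotone in the score;
#' plain water is always class A, and for other beverages the best
#' attainable class is B.
#'
#' @param score Integer score(s) within the category's attainable range.
#' @param category Food category.
#' @param tables Point tables from [ns_tables()].
#' @return Character vector of letter classes.
#' @export
classify_letter <- function(score, category, tables = ns_tables()) {
  .check_category(category)
  if (category == "water") return(rep("A", length(score)))
  rng <- score_extrema(category, tables)
  if (any(score < rng[1] | score > rng[2]))
    stop("score out of the attainable range [", rng[1], ", ", rng[2],
         "] for category '", category, "'")
  bands <- tables$categories[[category]]$letters
  idx <- rowSums(outer(score, as.numeric(bands$breaks), ">")) + 1L
  unlist(bands$labels)[idx]
}

#' Attainable score range of a category
#'
#' Computed by exhaustive combination of every component's attainable
#' point values (not by sampling), honouring the conditional protein rule,
#' so the result is exact for any table file.
#'
#' @param category Food category.
#' @param tables Point tables from [ns_tables()].
#' @return `c(min, max)` integer scores.
#' @examples
#' score_extrema("general_food")  # -17  55
#' @export
score_extrema <- function(category, tables = ns_tables()) {
  .check_category(category)
  if (category == "water") return(c(0L, 0L))
  # memoise for the shipped tables (classify_letter consults this per call)
  default_tables <- identical(tables, .ns_cache$tables)
  if (default_tables && !is.null(.ns_cache$extrema[[category]]))
    return(.ns_cache$extrema[[category]])
  cat_tab <- tables$categories[[category]]
  rule <- tables$protein_rule
  pts <- function(cmp) unique(as.integer(cat_tab$components[[cmp]]$points))
  a_sets <- lapply(cat_tab$unfavourable, pts)
  a_totals <- Reduce(function(x, y) unique(as.vector(outer(x, y, "+"))),
                     a_sets)
  fibre_set <- pts("fibre")
  fvl_set <- pts("fvl")
  protein_set <- pts("protein")
  if (category == "red_meat_product")
    protein_set <- unique(pmin(protein_set, as.integer(rule$red_meat_protein_cap)))
  scores <- integer(0)
  for (a in a_totals) {
    for (fvl in fvl_set) {
      p_set <- protein_set
      if (category %in% rule$applies_to && a >= rule$a_points_cutoff &&
          fvl < rule$fvl_full_points)
        p_set <- 0L
      c_totals <- unique(as.vector(outer(fibre_set, outer(fvl, p_set, "+"),
                                         "+")))
      scores <- c(scores, a - range(c_totals))
    }
  }
  out <- range(scores)
  if (default_tables) {
    if (is.null(.ns_cache$extrema)) .ns_cache$extrema <- list()
    .ns_cache$extrema[[category]] <- out
  }
  out
}

#' Score a food-composition table
#'
#' Batch interface over [compute_score()]: takes a data frame in the
#' standard food-composition layout (energy in kcal per 100 g, sodium
#' optionally in place of salt) and appends the point totals, score and
#' letter class.  Energy is converted to kJ (1 kcal = 4.184 kJ) and salt
#' from sodium (salt = sodium x 2.5) at ingestion, since Nutri-Score
#' thresholds are kJ- and salt-based while composition databases usually
#' report kcal and sometimes sodium.
#'
#' @param foods Data frame with columns `item_id`, `category`,
#'   `energy_kcal`, `sugars_g`, `satfat_g`, `totalfat_g`, `salt_g` (or
#'   `sodium_g`), `fibre_g`, `protein_g`, `fvl_pct`.
#' @param tables Point tables from [ns_tables()].
#' @return The input with columns `a_points`, `c_points`, `score`,
#'   `letter` appended.
#' @export
score_foods <- function(foods, tables = ns_tables()) {
  need <- c("item_id", "category", "energy_kcal", "sugars_g", "satfat_g",
            "totalfat_g", "fibre_g", "protein_g", "fvl_pct")
  miss <- setdiff(need, names(foods))
  if (length(miss))
    stop("food table is missing columns: ", paste(miss, collapse = ", "))
  if (!"salt_g" %in% names(foods)) {
    if (!"sodium_g" %in% names(foods))
      stop("food table needs a 'salt_g' or 'sodium_g' column")
    foods$salt_g <- foods$sodium_g * tables$units$salt_per_sodium
  }
  n <- nrow(foods)
  a <- c_ <- sc <- integer(n)
  lt <- character(n)
  for (i in seq_len(n)) {
    if (foods$category[i] == "water") {
      fs <- compute_score(NULL, "water", tables)
    } else {
      pr <- nutrient_profile(
        energy_kj = foods$energy_kcal[i] * tables$units$kj_per_kcal,
        sugars_g = foods$sugars_g[i], satfat_g = foods$satfat_g[i],
        totalfat_g = foods$totalfat_g[i], salt_g = foods$salt_g[i],
        fibre_g = foods$fibre_g[i], protein_g = foods$protein_g[i],
        fvl_pct = foods$fvl_pct[i])
      fs <- compute_score(pr, foods$category[i], tables)
    }
    a[i] <- fs$a_points; c_[i] <- fs$c_points
    sc[i] <- fs$score; lt[i] <- fs$letter
  }
  foods$a_points <- a
  foods$c_points <- c_
  foods$score <- sc
  foods$letter <- lt
  foods
}
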