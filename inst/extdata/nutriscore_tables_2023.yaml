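# 2023 updated Nutri-Score nutrient profiling model: component point tables.
# Transcribed from the official 2023 algorithm of the Nutri-Score
# international scientific committee (updated main foods, fats/oils/nuts/
# seeds, and beverages algorithms).
#
# Semantics: a value STRICTLY GREATER than thresholds[k] (1-based) earns
# points[k + 1]; a value at or below the first threshold earns points[1]
# (always 0).  Components with `boundary: ge` (the saturated-fat to total-fat
# ratio of the fats/oils/nuts/seeds category) instead award the next point
# band at values greater than OR EQUAL to the threshold, following the
# printed ratio table ("< 10" earns 0, "10 to < 16" earns 1, ...).
#
# Units: energy kJ/100 g (or /100 mL); sugars, saturated fat, salt, fibre,
# protein g/100 g (or /100 mL); fvl = % fruits, vegetables and legumes;
# satfat_ratio = 100 * saturated fat / total fat.
version: "uNS-NPM 2023"
units:
  kj_per_kcal: 4.184
  salt_per_sodium: 2.5

categories:
  general_food:
    unfavourable: [energy, sugars, saturated_fat, salt]
    favourable: [fibre, protein, fvl]
    components:
      energy:
        thresholds: [335, 670, 1005, 1340, 1675, 2010, 2345, 2680, 3015, 3350]
        points: [0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10]
      sugars:
        thresholds: [3.4, 6.8, 10, 14, 17, 20, 24, 27, 31, 34, 37, 41, 44, 48, 51]
        points: [0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15]
      saturated_fat:
        thresholds: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10]
        points: [0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10]
      salt:
        thresholds: [0.2, 0.4, 0.6, 0.8, 1.0, 1.2, 1.4, 1.6, 1.8, 2.0,
                     2.2, 2.4, 2.6, 2.8, 3.0, 3.2, 3.4, 3.6, 3.8, 4.0]
        points: [0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10,
                 11, 12, 13, 14, 15, 16, 17, 18, 19, 20]
      fibre:
        thresholds: [3.0, 4.1, 5.2, 6.3, 7.4]
        points: [0, 1, 2, 3, 4, 5]
      protein:
        thresholds: [2.4, 4.8, 7.2, 9.6, 12, 14, 17]
        points: [0, 1, 2, 3, 4, 5, 6, 7]
      fvl:
        thresholds: [40, 60, 80]
        points: [0, 1, 2, 5]
    letters:
      breaks: [0, 2, 10, 18]
      labels: [A, B, C, D, E]

  cheese:
    same_as: general_food

  red_meat_product:
    same_as: general_food

  fats_oils_nuts_seeds:
    same_as: general_food
    components:
      energy:
        thresholds: [120, 240, 360, 480, 600, 720, 840, 960, 1080, 1200]
        points: [0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10]
      satfat_ratio:
        thresholds: [10, 16, 22, 28, 34, 40, 46, 52, 58, 64]
        points: [0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10]
        boundary: ge
    unfavourable: [energy, sugars, satfat_ratio, salt]
    letters:
      breaks: [-6, 2, 10, 18]
      labels: [A, B, C, D, E]

  beverage:
    unfavourable: [energy, sugars, saturated_fat, salt]
    favourable: [fibre, protein, fvl]
    components:
      energy:
        thresholds: [30, 90, 150, 210, 240, 270, 300, 330, 360, 390]
        points: [0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10]
      sugars:
        thresholds: [0.5, 2, 3.5, 5, 6, 7, 8, 9, 10, 11]
        points: [0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10]
      saturated_fat:
        thresholds: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10]
        points: [0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10]
      salt:
        thresholds: [0.2, 0.4, 0.6, 0.8, 1.0, 1.2, 1.4, 1.6, 1.8, 2.0,
                     2.2, 2.4, 2.6, 2.8, 3.0, 3.2, 3.4, 3.6, 3.8, 4.0]
        points: [0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10,
                 11, 12, 13, 14, 15, 16, 17, 18, 19, 20]
      fibre:
        thresholds: [3.0, 4.1, 5.2, 6.3, 7.4]
        points: [0, 1, 2, 3, 4, 5]
      protein:
        thresholds: [1.2, 1.5, 1.8, 2.1, 2.4, 2.7, 3.0]
        points: [0, 1, 2, 3, 4, 5, 6, 7]
      fvl:
        thresholds: [40, 60, 80]
        points: [0, 2, 4, 6]
    letters:
      # A is reserved for plain water; scored beverages start at B.
      breaks: [2, 6, 9]
      labels: [B, C, D, E]

# Conditional protein rule: when a food's unfavourable total reaches
# `a_points_cutoff`, protein points are not counted unless the food earns
# the full fruit/vegetable/legume component (`fvl_full_points`).  Cheese is
# exempt (protein always counted); beverages are not subject to the rule.
# Red meat and products thereof have protein points capped at
# `red_meat_protein_cap` regardless.
protein_rule:
  a_points_cutoff: 11
  fvl_full_points: 5
  applies_to: [general_food, red_meat_product, fats_oils_nuts_seeds]
  red_meat_protein_cap: 2
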