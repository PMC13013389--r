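#' @keywords internal
"_PACKAGE"

# Food categories recognised by the scoring engine.  `water` bypasses the
# point tables entirely (best class, numeric score 0).
NS_CATEGORIES <- c("general_food", "beverage", "fats_oils_nuts_seeds",
                   "cheese", "red_meat_product", "water")

.ns_cache <- new.env(parent = emptyenv())

#' Load the Nutri-Score point tables
#'
#' Reads the versioned, human-readable YAML file holding the 2023
#' Nutri-Score component point tables, letter-class bands and the
#' conditional protein rule, resolves `same_as` category references, and
#' validates the structural invariants (strictly increasing thresholds,
#' points starting at 0 and increasing, one more point band than
#' thresholds).
#'
#' The scoring code is entirely table-driven: correcting a transcription in
#' the YAML file never touches logic.
#'
#' @param path Path to a point-table YAML file.  Defaults to the 2023
#'   tables shipped with the package.
#' @return A list with elements `categories` (per category: `components`,
#'   `unfavourable`, `favourable`, `letters`), `protein_rule`, `units` and
#'   `version`, of class `ns_tables`.
#' @examples
#' tab <- ns_tables()
#' names(tab$categories)
#' @export
ns_tables <- function(path = NULL) {
  default <- is.null(path)
  if (default) {
    if (!is.null(.ns_cache$tables)) return(.ns_cache$tables)
    path <- system.file("extdata", "nutriscore_tables_2023.yaml",
                        package = "nutriscox", mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)
  cats <- raw$categories
  # resolve same_as references (may override individual components)
  for (nm in names(cats)) {
    base <- cats[[nm]]$same_as
    if (!is.null(base)) {
      merged <- cats[[base]]
      over <- cats[[nm]]
      over$same_as <- NULL
      merged$components <- utils::modifyList(merged$components,
                                             over$components %||% list())
      for (f in setdiff(names(over), "components")) merged[[f]] <- over[[f]]
      cats[[nm]] <- merged
    }
  }
  for (nm in names(cats)) {
    for (cmp in names(cats[[nm]]$components)) {
      tb <- cats[[nm]]$components[[cmp]]
      th <- as.numeric(tb$thresholds)
      pt <- as.numeric(tb$points)
      if (length(pt) != length(th) + 1L)
        stop("point table ", nm, "/", cmp,
             ": need one more point band than thresholds")
      if (any(diff(th) <= 0))
        stop("point table ", nm, "/", cmp,
             ": thresholds must be strictly increasing")
      if (pt[1] != 0 || any(diff(pt) <= 0))
        stop("point table ", nm, "/", cmp,
             ": points must start at 0 and be strictly increasing")
      cats[[nm]]$components[[cmp]]$thresholds <- th
      cats[[nm]]$components[[cmp]]$points <- pt
    }
  }
  out <- structure(list(categories = cats,
                        protein_rule = raw$protein_rule,
                        units = raw$units,
                        version = raw$version),
                   class = "ns_tables")
  if (default) .ns_cache$tables <- out
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Look up the points earned by one scoring component
#'
#' Returns the point band for a component value against the threshold list
#' of the given category.  The boundary convention is "strictly greater": a
#' value exactly equal to a threshold earns the lower point count.  The
#' saturated-fat ratio component of the fats/oils/nuts/seeds category is
#' the one table using greater-or-equal boundaries (declared in the table
#' file), matching its printed "10 to < 16" style bands.
#'
#' @param component Component name, e.g. `"sugars"`, `"energy"`, `"fvl"`.
#' @param value Amount per 100 g (or 100 mL); energy in kJ.  Vectorised.
#' @param category One of the scored food categories.
#' @param tables Point tables from [ns_tables()].
#' @return Integer points, never exceeding the component maximum.
#' @examples
#' points_for_component("sugars", c(0, 5, 60), "general_food")
#' @export
points_for_component <- function(component, value, category,
                                 tables = ns_tables()) {
  cat_tab <- tables$categories[[category]]
  if (is.null(cat_tab))
    stop("unknown category '", category, "' for component '", component, "'")
  tb <- cat_tab$components[[component]]
  if (is.null(tb))
    stop("component '", component,
         "' is not defined for category '", category, "'")
  if (any(value < 0 & component != "satfat_ratio"))
    stop("negative value for component '", component, "'")
  idx <- if (identical(tb$boundary, "ge")) {
    rowSums(outer(value, tb$thresholds, ">="))
  } else {
    rowSums(outer(value, tb$thresholds, ">"))
  }
  as.integer(tb$points[idx + 1L])
}
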