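#' Geographic hierarchy
#'
#' Countries are organised in a five-level tree: a single global root,
#' country income groups, continents, regions and countries. Every country
#' has exactly one ancestor at each of the four upper levels. The hierarchy
#' is the backbone of hierarchical parameter priors: a country-level value is
#' the sum, on the transformed scale, of offsets along its ancestor path.
#'
#' @param nodes data.frame with columns `id`, `level`
#'   (one of `"global"`, `"income_group"`, `"continent"`, `"region"`,
#'   `"country"`) and `parent` (`NA` for the global root only).
#' @return An object of class `geo_hierarchy` (validated node table).
#' @export
geo_hierarchy <- function(nodes) {
  stopifnot(is.data.frame(nodes),
            all(c("id", "level", "parent") %in% names(nodes)))
  nodes <- nodes[, c("id", "level", "parent")]
  nodes$id <- as.character(nodes$id)
  nodes$level <- as.character(nodes$level)
  nodes$parent <- as.character(nodes$parent)
  if (anyDuplicated(nodes$id)) stop("duplicate node ids", call. = FALSE)
  if (!all(nodes$level %in% .geo_levels)) {
    stop("unknown hierarchy level(s): ",
         paste(setdiff(nodes$level, .geo_levels), collapse = ", "),
         call. = FALSE)
  }
  root <- nodes$id[nodes$level == "global"]
  if (length(root) != 1L || !is.na(nodes$parent[nodes$level == "global"])) {
    stop("hierarchy must have exactly one global root with no parent",
         call. = FALSE)
  }
  nonroot <- nodes[nodes$level != "global", ]
  if (anyNA(nonroot$parent) || !all(nonroot$parent %in% nodes$id)) {
    stop("every non-global node needs an existing parent", call. = FALSE)
  }
  # parent must sit exactly one level up
  lvl <- match(nodes$level, .geo_levels)
  plvl <- lvl[match(nodes$parent, nodes$id)]
  bad <- !is.na(plvl) & plvl != lvl - 1L
  if (any(bad)) {
    stop("parent of ", paste(nodes$id[bad], collapse = ", "),
         " is not one level up", call. = FALSE)
  }
  structure(nodes, class = c("geo_hierarchy", "data.frame"))
}

.geo_levels <- c("global", "income_group", "continent", "region", "country")

#' Ancestor path of a country
#'
#' @param hierarchy a [geo_hierarchy()].
#' @param country a country node id.
#' @return Named character vector of node ids, one per level
#'   (global, income_group, continent, region, country).
#' @export
country_path <- function(hierarchy, country) {
  stopifnot(inherits(hierarchy, "geo_hierarchy"))
  i <- match(country, hierarchy$id)
  if (is.na(i) || hierarchy$level[i] != "country") {
    stop("country '", country, "' not in hierarchy", call. = FALSE)
  }
  path <- character(5L)
  names(path) <- .geo_levels
  while (!is.na(i)) {
    path[hierarchy$level[i]] <- hierarchy$id[i]
    i <- match(hierarchy$parent[i], hierarchy$id)
  }
  path
}

#' List countries in a hierarchy
#' @param hierarchy a [geo_hierarchy()].
#' @return Character vector of country node ids.
#' @export
countries_of <- function(hierarchy) {
  stopifnot(inherits(hierarchy, "geo_hierarchy"))
  hierarchy$id[hierarchy$level == "country"]
}
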