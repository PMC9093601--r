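# Declarative AND/NOT region-of-interest recipes for tract selection.
# A recipe is a tract name, its laterality and an ordered list of gates;
# each gate is a plane (axial / coronal / sagittal / parasagittal), a
# polarity, and a landmark-relative placement rule that can be resolved to
# a voxel mask against any reference geometry that supplies the named
# structures. Placements are anatomical (fractions of a structure's
# anterior-posterior extent, slices at structure edges, midline planes),
# never hard-coded slice indices, so one recipe file serves every subject.

STUDY_TRACTS <- c("gCC", "bCC", "ATR", "IFO", "ILF", "PLIC", "PTR", "UF")

#' Construct a single ROI gate
#'
#' @param polarity "AND" (streamline must intersect) or "NOT" (must avoid).
#' @param plane "axial", "coronal", "sagittal" or "parasagittal".
#' @param placement named list describing the landmark-relative rule:
#'   `type` one of "fraction" (slab over a fraction of a structure's
#'   anterior-posterior extent; fields `structure`, `from`, `to`, measured
#'   from `edge` = "anterior" or "posterior"), "slice" (slab at a structure
#'   edge; fields `structure`, `edge` in anterior/posterior/superior/
#'   inferior/lateral, optional `offset_mm`), "at_center" (slab at the
#'   structure's centre along the plane normal), "midline" (the central
#'   sagittal plane), "lateral_of" (parasagittal region lateral to a
#'   structure's edge; requires a side).
#' @param extent "entire" (full in-plane extent), "structure" (in-plane
#'   bounding extent of `extent_structure`, defaulting to the placement
#'   structure) or "complement_structure" (in-plane complement of it).
#' @param side "left", "right", "both" or "n/a"; parasagittal gates must
#'   carry a side.
#' @param extent_structure structure naming the in-plane region when
#'   `extent` is not "entire".
#' @return object of class `roi_gate`.
#' @export
roi_gate <- function(polarity = c("AND", "NOT"),
                     plane = c("axial", "coronal", "sagittal",
                               "parasagittal"),
                     placement,
                     extent = c("entire", "structure",
                                "complement_structure"),
                     side = "n/a",
                     extent_structure = NULL) {
  polarity <- match.arg(polarity)
  plane <- match.arg(plane)
  extent <- match.arg(extent)
  stopifnot(is.list(placement), !is.null(placement$type))
  if (plane == "parasagittal" && !side %in% c("left", "right", "both")) {
    stop("parasagittal gates must carry a side (left/right/both)")
  }
  if (extent != "entire" && is.null(extent_structure)) {
    extent_structure <- placement$structure
  }
  structure(list(polarity = polarity, plane = plane, placement = placement,
                 extent = extent, side = side,
                 extent_structure = extent_structure),
            class = "roi_gate")
}

#' Construct a tract recipe
#'
#' @param tract one of gCC, bCC, ATR, IFO, ILF, PLIC, PTR, UF.
#' @param laterality "midline" or "bilateral".
#' @param gates list of [roi_gate()]s; at least one AND gate is required.
#' @return object of class `tract_recipe`.
#' @export
tract_recipe <- function(tract, laterality = c("midline", "bilateral"),
                         gates) {
  laterality <- match.arg(laterality)
  if (!tract %in% STUDY_TRACTS) {
    stop("unknown tract '", tract, "'; expected one of ",
         paste(STUDY_TRACTS, collapse = ", "))
  }
  gates <- lapply(gates, function(g) {
    if (!inherits(g, "roi_gate")) do.call(roi_gate, g) else g
  })
  if (!any(vapply(gates, function(g) g$polarity == "AND", logical(1)))) {
    stop("recipe for ", tract, " has no AND gate")
  }
  structure(list(tract = tract, laterality = laterality, gates = gates),
            class = "tract_recipe")
}

#' @export
print.tract_recipe <- function(x, ...) {
  cat("Recipe ", x$tract, " (", x$laterality, "): ",
      length(x$gates), " gates [",
      paste(vapply(x$gates, function(g)
        paste0(g$polarity, ":", g$plane), character(1)), collapse = ", "),
      "]\n", sep = "")
  invisible(x)
}

#' Load tract recipes from a YAML file
#'
#' The shipped default (`system.file("extdata", "table1_recipes.yaml",
#' package = "pseudotract")`) encodes the eight study tracts; its two
#' midline and six bilateral recipes expand to 14 tract instances per
#' subject.
#'
#' @param path YAML recipe file; one document per tract.
#' @return list of `tract_recipe` objects.
#' @export
load_recipes <- function(path = default_recipe_path()) {
  if (!file.exists(path)) stop("recipe file not found: ", path)
  docs <- yaml::read_yaml(path)
  if (!is.null(docs$tract)) docs <- list(docs)
  recipes <- lapply(docs, function(doc) {
    if (is.null(doc$tract)) stop("recipe document missing 'tract'")
    if (is.null(doc$laterality)) {
      stop("recipe for ", doc$tract, " missing laterality")
    }
    if (is.null(doc$gates) || !length(doc$gates)) {
      stop("recipe for ", doc$tract, " has no gates")
    }
    tract_recipe(doc$tract, doc$laterality, doc$gates)
  })
  names(recipes) <- vapply(recipes, `[[`, character(1), "tract")
  if (anyDuplicated(names(recipes))) stop("duplicate tract recipes in file")
  recipes
}

#' Path of the shipped default recipe file
#' @export
default_recipe_path <- function() {
  system.file("extdata", "table1_recipes.yaml", package = "pseudotract",
              mustWork = TRUE)
}

#' Expand recipes to per-subject tract instances
#'
#' Midline recipes yield one instance; bilateral recipes yield a left and a
#' right instance.
#'
#' @param recipes list of `tract_recipe` objects.
#' @return data.frame with columns `tract`, `side`.
#' @export
expand_instances <- function(recipes) {
  rows <- lapply(recipes, function(r) {
    if (r$laterality == "midline") {
      data.frame(tract = r$tract, side = "midline")
    } else {
      data.frame(tract = rep(r$tract, 2), side = c("left", "right"))
    }
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Count attempted tract extractions for a cohort
#'
#' Each subject contributes one instance per midline recipe and two per
#' bilateral recipe.
#'
#' @param recipes list of `tract_recipe` objects.
#' @param n_subjects cohort size.
#' @return integer count.
#' @export
attempted_count <- function(recipes, n_subjects) {
  n_mid <- sum(vapply(recipes, function(r) r$laterality == "midline",
                      logical(1)))
  n_bil <- length(recipes) - n_mid
  as.integer(n_subjects) * (n_mid + 2L * n_bil)
}
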