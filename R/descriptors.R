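# Structure-derived physicochemical descriptors: molecular weight from an
# element-count record and topological polar surface area as an Ertl
# fragment-contribution sum over named polar groups.

#' Build a molecule composition record
#'
#' A composition record holds element counts and, optionally, counts of
#' named polar groups. It is the input both to [molecular_weight()] and to
#' [tpsa_ertl()]. Full structure perception (SMILES parsing, automatic
#' group detection) is deliberately out of scope: the composition is a
#' plain count record so that every descriptor is reproducible from the
#' printed formula alone. An external perception step may populate the
#' record, but nothing here requires one.
#'
#' @param elements Either a chemical formula string such as `"C30H48O3"`
#'   or a named numeric vector/list of element counts, e.g.
#'   `c(C = 30, H = 48, O = 3)`.
#' @param groups Optional named numeric vector/list of polar-group counts
#'   using the group names of [ertl_contributions()], e.g.
#'   `c(carboxylic_acid = 1, hydroxyl = 1)`. Group counts describe how the
#'   polar atoms are arranged; the atoms themselves are already included in
#'   `elements`.
#' @return An object of class `molecule_composition`.
#' @export
#' @examples
#' oa <- molecule_composition("C30H48O3",
#'                            groups = c(carboxylic_acid = 1, hydroxyl = 1))
#' molecular_weight(oa)
#' tpsa_ertl(oa)
molecule_composition <- function(elements, groups = NULL) {
  if (is.character(elements) && length(elements) == 1) {
    elements <- parse_formula(elements)
  }
  elements <- unlist(elements)
  if (is.null(names(elements)) || any(names(elements) == "")) {
    stop_bbb("element counts must be named by element symbol")
  }
  if (any(elements < 0) || any(elements != round(elements))) {
    stop_bbb("element counts must be non-negative integers")
  }
  groups <- unlist(groups %||% numeric())
  if (length(groups) > 0) {
    if (is.null(names(groups)) || any(names(groups) == "")) {
      stop_bbb("polar-group counts must be named")
    }
    if (any(groups < 0) || any(groups != round(groups))) {
      stop_bbb("polar-group counts must be non-negative integers")
    }
  }
  structure(
    list(elements = elements, groups = groups),
    class = "molecule_composition"
  )
}

#' @export
print.molecule_composition <- function(x, ...) {
  f <- paste0(names(x$elements), ifelse(x$elements == 1, "", x$elements),
              collapse = "")
  cat("<molecule_composition> ", f, "\n", sep = "")
  if (length(x$groups)) {
    cat("  polar groups:",
        paste0(names(x$groups), " x", x$groups, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Parse a Hill-style chemical formula
#'
#' @param formula A string such as `"C30H48O3"` or `"H2O"`.
#' @return A named numeric vector of element counts.
#' @export
#' @examples
#' parse_formula("C30H48O3")
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1)
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", formula)) {
    stop_bbb("cannot parse chemical formula: ", formula)
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  sym <- sub("[0-9]+$", "", tokens)
  n <- as.numeric(sub("^[A-Za-z]+", "", tokens))
  n[is.na(n)] <- 1
  counts <- vapply(unique(sym), function(s) sum(n[sym == s]), numeric(1))
  counts
}

#' Molecular weight from a composition record
#'
#' Sum of count times standard atomic weight over all elements, using the
#' packaged IUPAC conventional weights ([atomic_weights()]). Additive over
#' disjoint compositions; full precision is returned, so round only when
#' reporting.
#'
#' @param composition A [molecule_composition()], a formula string, or a
#'   named element-count vector.
#' @return Molecular weight in g/mol.
#' @export
#' @examples
#' molecular_weight("C30H48O3")  # oleanolic acid, 456.7 at 1 decimal
molecular_weight <- function(composition) {
  composition <- as_composition(composition)
  counts <- composition$elements
  weights <- atomic_weights()
  idx <- match(names(counts), weights$element)
  if (anyNA(idx)) {
    stop_bbb("unknown element symbol(s): ",
             paste(names(counts)[is.na(idx)], collapse = ", "))
  }
  sum(counts * weights$weight[idx])
}

#' Topological polar surface area (Ertl fragment sum)
#'
#' Sum of count times fragment contribution over the composition's polar
#' groups, using the packaged published contributions
#' ([ertl_contributions()]). A pure hydrocarbon has TPSA 0. The sum is
#' additive and monotone non-decreasing in every group count.
#'
#' @param composition A [molecule_composition()] carrying polar-group
#'   counts, or a named group-count vector.
#' @return Polar surface area in square Angstroms.
#' @export
#' @examples
#' tpsa_ertl(c(carboxylic_acid = 1, hydroxyl = 1))  # 57.53
tpsa_ertl <- function(composition) {
  if (is.numeric(composition) && !is.null(names(composition))) {
    composition <- molecule_composition(elements = c(C = 0),
                                        groups = composition)
  }
  if (!inherits(composition, "molecule_composition")) {
    stop_bbb("`composition` must be a molecule_composition or a named ",
             "group-count vector")
  }
  groups <- composition$groups
  if (length(groups) == 0) return(0)
  contrib <- ertl_contributions()
  idx <- match(names(groups), contrib$group)
  if (anyNA(idx)) {
    stop_bbb("unknown polar-group name(s): ",
             paste(names(groups)[is.na(idx)], collapse = ", "),
             "; see ertl_contributions() for the packaged set")
  }
  sum(groups * contrib$contribution[idx])
}

#' Read a composition record from a JSON file
#'
#' Expects the layout `{"elements": {"C": 30, ...}, "groups": {...}}`.
#'
#' @param path Path to a JSON file.
#' @return A [molecule_composition()].
#' @export
read_composition_json <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  molecule_composition(elements = rec$elements, groups = rec$groups)
}

as_composition <- function(x) {
  if (inherits(x, "molecule_composition")) return(x)
  if (is.character(x)) return(molecule_composition(x))
  if (is.numeric(x) && !is.null(names(x))) return(molecule_composition(x))
  stop_bbb("cannot interpret `composition`; use molecule_composition()")
}
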