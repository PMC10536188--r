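# Post-docking ligand-protein contact mapping: heavy-atom distances in nm,
# a strict distance cutoff for residue contacts, and distance-window
# classification into hydrogen bonds, non-polar C-C contacts, CH-pi
# contacts with aromatic side chains, and other polar contacts.

POLAR_ELEMENTS <- c("N", "O")
# intra-ligand bond detection threshold (nm); covers C-O/C-N/C-C bonds
BOND_CUTOFF_NM <- 0.18

#' Parse a PDB structure into a flat atom table
#'
#' Reads ATOM/HETATM records (via bio3d) into a tibble with coordinates
#' converted from Angstroms to nanometres. The element is taken from PDB
#' columns 77-78 when present, falling back to the atom name; hydrogens
#' are retained but flagged (`is_hydrogen`) and ignored by the contact
#' analysis, which is a heavy-atom convention. Records too short or with
#' unparseable coordinates are skipped with a warning.
#'
#' @param x Path to a PDB file, or a character vector / single string of
#'   PDB text.
#' @param ligand_resname,ligand_chain Optional ligand selector: atoms with
#'   this residue name (or chain) are marked as the ligand.
#' @return An object of class `structure_model`: list with the `atoms`
#'   tibble and the ligand selector.
#' @export
parse_structure <- function(x, ligand_resname = NULL, ligand_chain = NULL) {
  lines <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    readLines(x)
  } else if (length(x) == 1) {
    strsplit(x, "\n")[[1]]
  } else {
    x
  }
  rec <- grepl("^(ATOM  |HETATM)", lines)
  atom_lines <- lines[rec]
  if (length(atom_lines) == 0) {
    stop_bbb("no ATOM/HETATM records found in PDB input")
  }
  ok <- nchar(atom_lines) >= 54 &
    !is.na(suppressWarnings(as.numeric(substr(atom_lines, 31, 38)))) &
    !is.na(suppressWarnings(as.numeric(substr(atom_lines, 39, 46)))) &
    !is.na(suppressWarnings(as.numeric(substr(atom_lines, 47, 54))))
  if (any(!ok)) {
    warning(sum(!ok), " malformed ATOM/HETATM record(s) skipped",
            call. = FALSE)
    atom_lines <- atom_lines[ok]
  }
  if (length(atom_lines) == 0) {
    stop_bbb("no parseable ATOM/HETATM records in PDB input")
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(c(atom_lines, "END"), tmp)
  pdb <- bio3d::read.pdb(tmp, verbose = FALSE)
  a <- pdb$atom

  element <- toupper(trimws(a$elesy))
  fallback <- element == "" | is.na(element)
  if (any(fallback)) {
    element[fallback] <- infer_element(a$elety[fallback])
  }
  atoms <- tibble::tibble(
    serial = a$eleno,
    element = element,
    atom_name = trimws(a$elety),
    residue_name = trimws(a$resid),
    residue_number = a$resno,
    chain = ifelse(is.na(a$chain) | a$chain == "", " ", a$chain),
    record = a$type,
    x = a$x / 10, y = a$y / 10, z = a$z / 10,  # Angstrom -> nm
    is_hydrogen = element %in% c("H", "D")
  )
  if (any(!is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    stop_bbb("non-finite coordinates in PDB input")
  }
  structure(
    list(atoms = atoms,
         ligand_resname = ligand_resname,
         ligand_chain = ligand_chain),
    class = "structure_model"
  )
}

# atom-name based element fallback: strip leading digits, then match the
# leading letters against known two-letter elements before defaulting to
# the first letter
infer_element <- function(atom_name) {
  nm <- toupper(gsub("^[0-9']+", "", trimws(atom_name)))
  letters_only <- gsub("[^A-Z]", "", nm)
  two <- substr(letters_only, 1, 2)
  known2 <- c("FE", "ZN", "MG", "CL", "BR", "NA", "CA")
  # CA/NA in a residue context are almost always alpha-carbon / backbone N,
  # so only accept two-letter symbols that cannot be organic atom names
  out <- substr(letters_only, 1, 1)
  ion <- two %in% setdiff(known2, c("CA", "NA")) & nchar(nm) == nchar(two)
  out[ion] <- two[ion]
  out
}

#' @export
print.structure_model <- function(x, ...) {
  cat("<structure_model>", nrow(x$atoms), "atoms,",
      nrow(dplyr::distinct(x$atoms, .data$residue_name,
                           .data$residue_number, .data$chain)),
      "residues\n")
  sel <- ligand_mask(x, quiet = TRUE)
  if (!is.null(sel)) cat("  ligand atoms:", sum(sel), "\n")
  invisible(x)
}

#' Mark the ligand within a parsed structure
#'
#' @param structure A `structure_model`.
#' @param resname,chain Ligand residue name and/or chain.
#' @return The updated `structure_model`.
#' @export
set_ligand <- function(structure, resname = NULL, chain = NULL) {
  stopifnot(inherits(structure, "structure_model"))
  structure$ligand_resname <- resname
  structure$ligand_chain <- chain
  structure
}

ligand_mask <- function(structure, quiet = FALSE) {
  a <- structure$atoms
  sel <- rep(TRUE, nrow(a))
  any_selector <- FALSE
  if (!is.null(structure$ligand_resname)) {
    sel <- sel & a$residue_name %in% structure$ligand_resname
    any_selector <- TRUE
  }
  if (!is.null(structure$ligand_chain)) {
    sel <- sel & a$chain %in% structure$ligand_chain
    any_selector <- TRUE
  }
  if (!any_selector) {
    if (quiet) return(NULL)
    stop_bbb("no ligand selector set; use set_ligand() or the ",
             "ligand_resname/ligand_chain arguments of parse_structure()")
  }
  sel
}

# heavy-atom ligand/protein split
split_complex <- function(structure) {
  sel <- ligand_mask(structure)
  a <- structure$atoms
  lig <- a[sel & !a$is_hydrogen, ]
  prot <- a[!sel & !a$is_hydrogen, ]
  if (nrow(lig) == 0) stop_bbb("ligand selector matches no heavy atoms")
  if (nrow(prot) == 0) stop_bbb("no protein heavy atoms outside the ligand")
  list(ligand = lig, protein = prot)
}

# pairwise distance matrix (nm) between two atom tables
atom_distances <- function(a, b) {
  ca <- as.matrix(a[, c("x", "y", "z")])
  cb <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(ca^2), rowSums(cb^2), "+") - 2 * ca %*% t(cb)
  sqrt(pmax(d2, 0))
}

#' Residues in contact with the ligand
#'
#' A residue is in contact when any of its heavy atoms lies strictly
#' closer than `cutoff` to any ligand heavy atom. The report is sorted by
#' minimum heavy-atom distance and is, by construction, monotone in the
#' cutoff: enlarging the cutoff can only add residues.
#'
#' @param structure A `structure_model` with a ligand selector.
#' @param cutoff Contact cutoff in nm (default 0.38; a robustness check at
#'   0.45 is conventional).
#' @return A `contact_report`: tibble with columns `residue_name`,
#'   `residue_number`, `chain`, `min_distance_nm`, plus the cutoff as an
#'   attribute.
#' @export
contact_residues <- function(structure, cutoff = 0.38) {
  check_number(cutoff, "cutoff", positive = TRUE)
  parts <- split_complex(structure)
  D <- atom_distances(parts$ligand, parts$protein)
  min_d <- apply(D, 2, min)
  prot <- parts$protein
  report <- tibble::tibble(
    residue_name = prot$residue_name,
    residue_number = prot$residue_number,
    chain = prot$chain,
    min_distance_nm = min_d
  ) |>
    dplyr::group_by(.data$residue_name, .data$residue_number, .data$chain) |>
    dplyr::summarise(min_distance_nm = min(.data$min_distance_nm),
                     .groups = "drop") |>
    dplyr::filter(.data$min_distance_nm < cutoff) |>
    dplyr::arrange(.data$min_distance_nm)
  attr(report, "cutoff") <- cutoff
  class(report) <- c("contact_report", class(report))
  report
}

#' Classify ligand-residue contacts by distance windows
#'
#' Every contact residue is assigned the classes supported by at least one
#' of its heavy-atom pairs with the ligand (windows closed on both ends;
#' boundary ties included):
#'
#' * `hydrogen_bond` - an O/N ligand atom and an O/N residue atom at
#'   0.25-0.35 nm, the typical donor-acceptor distance range;
#' * `nonpolar_CC` - a carbon-carbon pair at 0.30-0.38 nm;
#' * `CH_pi` - a ligand aliphatic carbon (one with no polar neighbour
#'   within the ligand, a proxy for an sp3 C-H carbon) within the cutoff
#'   of an aromatic ring atom of Phe/Tyr/Trp/His (packaged ring-atom-name
#'   table, [aromatic_ring_atoms()]);
#' * `other_polar` - any other pair within the cutoff involving at least
#'   one O/N atom.
#'
#' The criteria are distance-only (no angular terms), matching the
#' convention of cutoff-based post-docking analysis.
#'
#' @param structure The `structure_model` the report was computed from.
#' @param report A [contact_residues()] report; computed on the fly when
#'   omitted.
#' @param cutoff Contact cutoff in nm; defaults to the report's.
#' @return The report with a list-column `classes` and a collapsed
#'   `classes_str` column appended.
#' @export
classify_contacts <- function(structure, report = NULL, cutoff = NULL) {
  if (is.null(report)) report <- contact_residues(structure,
                                                  cutoff %||% 0.38)
  cutoff <- cutoff %||% attr(report, "cutoff") %||% 0.38
  parts <- split_complex(structure)
  lig <- parts$ligand
  prot <- parts$protein
  ring <- aromatic_ring_atoms()

  # ligand aliphatic carbons: no O/N neighbour within bonding distance
  lig_c <- lig$element == "C"
  lig_polar <- lig$element %in% POLAR_ELEMENTS
  aliphatic <- lig_c
  if (any(lig_polar) && any(lig_c)) {
    Dl <- atom_distances(lig[lig_c, ], lig[lig_polar, ])
    aliphatic[lig_c] <- apply(Dl, 1, min) > BOND_CUTOFF_NM
  }

  D <- atom_distances(lig, prot)
  classes <- purrr::pmap(
    list(report$residue_name, report$residue_number, report$chain),
    function(rn, rno, ch) {
      pc <- which(prot$residue_name == rn & prot$residue_number == rno &
                    prot$chain == ch)
      d <- D[, pc, drop = FALSE]
      within <- d < cutoff
      cl <- character()
      p_polar <- prot$element[pc] %in% POLAR_ELEMENTS
      hb <- outer(lig_polar, p_polar, "&") & d >= 0.25 & d <= 0.35
      if (any(hb)) cl <- c(cl, "hydrogen_bond")
      cc <- outer(lig$element == "C", prot$element[pc] == "C", "&") &
        d >= 0.30 & d <= 0.38
      if (any(cc)) cl <- c(cl, "nonpolar_CC")
      ring_atoms <- ring$atom_name[ring$residue == rn]
      if (length(ring_atoms) > 0) {
        p_ring <- prot$atom_name[pc] %in% ring_atoms
        chpi <- outer(aliphatic, p_ring, "&") & within
        if (any(chpi)) cl <- c(cl, "CH_pi")
      }
      polar_any <- outer(lig_polar, p_polar, "|") & within &
        !(outer(lig_polar, p_polar, "&") & d >= 0.25 & d <= 0.35)
      if (any(polar_any)) cl <- c(cl, "other_polar")
      cl
    }
  )
  report$classes <- classes
  report$classes_str <- purrr::map_chr(classes, \(cl) {
    if (length(cl) == 0) "" else paste(cl, collapse = ",")
  })
  report
}

#' Write / format a contact report
#'
#' `write_contact_report()` emits a TSV (residue, min distance, classes);
#' `format_contact_report()` returns human-readable lines mirroring the
#' conventional per-residue interaction listing.
#'
#' @param report A (classified) `contact_report`.
#' @param path Output path.
#' @export
write_contact_report <- function(report, path) {
  out <- tibble::as_tibble(report)
  out$classes <- NULL
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_contact_report
#' @export
format_contact_report <- function(report) {
  purrr::pmap_chr(
    list(report$residue_name, report$residue_number,
         report$min_distance_nm,
         if ("classes_str" %in% names(report)) report$classes_str
         else rep("", nrow(report))),
    function(rn, rno, d, cl) {
      pretty <- paste0(substr(rn, 1, 1), tolower(substring(rn, 2)))
      sprintf("%s%d  min %.3f nm%s", pretty, rno, d,
              if (nzchar(cl)) paste0("  [", cl, "]") else "")
    }
  )
}

#' @export
autoplot.contact_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$residue <- paste0(df$residue_name, df$residue_number)
  df$residue <- factor(df$residue, levels = rev(df$residue))
  df$class <- if ("classes_str" %in% names(df)) {
    sub(",.*", "", df$classes_str)
  } else {
    "contact"
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$min_distance_nm, .data$residue,
                                   fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = attr(object, "cutoff") %||% 0.38,
                        linetype = 3) +
    ggplot2::labs(x = "min heavy-atom distance (nm)", y = NULL) +
    ggplot2::theme_minimal()
}
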