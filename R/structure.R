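#' Default heavy-atom van der Waals radius table
#'
#' Radii in Angstrom for the elements that dominate nucleic-acid and protein
#' structures (Bondi-style values: C 1.70, N 1.55, O 1.52, P 1.80, S 1.80).
#' Unknown element symbols fall back to `default` with a warning at parse
#' time.
#'
#' @param default Fallback radius (Angstrom) for element symbols absent from
#'   the table.
#' @return Named numeric vector of radii with a `default` attribute.
#' @export
default_vdw_radii <- function(default = 1.70) {
  r <- c(C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80,
         SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
  attr(r, "default") <- default
  r
}

# residue names treated as solvent or monoatomic ions and dropped at parse
.solvent_resids <- c("HOH", "WAT", "DOD", "H2O", "SOL")
.ion_resids <- c("NA", "K", "MG", "CA", "CL", "ZN", "MN", "FE", "NI", "CU",
                 "CO", "CD", "SR", "BA", "CS", "RB", "LI", "BR", "IOD", "F",
                 "OS", "IR", "PT", "NH4", "SO4", "PO4")

#' Parse an atomic structure into a structure model
#'
#' Reads a PDB or mmCIF file and retains the heavy atoms of the first model:
#' hydrogens (and deuteriums), waters and common ions are excluded, and each
#' remaining atom is assigned a van der Waals radius from `radii`.
#'
#' @param path Path to a structure file.
#' @param format One of `"auto"` (by extension), `"pdb"`, `"cif"`.
#' @param radii Named radius table, see [default_vdw_radii()].
#' @return A `structure_model`: list with `atoms` (data frame with columns
#'   `chain`, `resno`, `resid`, `elety`, `elesy`, `x`, `y`, `z`, `radius`,
#'   `hetero`), `source_id` and `model_index`.
#' @export
parse_structure <- function(path, format = c("auto", "pdb", "cif"),
                            radii = default_vdw_radii()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
    else bio3d::read.cif(path, verbose = FALSE),
    error = function(e) stop("failed to parse '", path, "' as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  elesy <- toupper(trimws(as.character(at$elesy)))
  guess <- toupper(substr(gsub("^[0-9']+", "", trimws(at$elety)), 1, 1))
  elesy[is.na(elesy) | elesy == ""] <- guess[is.na(elesy) | elesy == ""]

  resid <- toupper(trimws(at$resid))
  keep <- !(elesy %in% c("H", "D")) &
    !(resid %in% .solvent_resids) &
    !(resid %in% .ion_resids)
  at <- at[keep, , drop = FALSE]
  elesy <- elesy[keep]
  resid <- resid[keep]
  if (nrow(at) == 0L)
    stop("no atoms left after filtering hydrogens, waters and ions: ", path)

  radius <- unname(radii[elesy])
  if (anyNA(radius)) {
    unknown <- sort(unique(elesy[is.na(radius)]))
    warning("unknown element symbol(s) ", paste(unknown, collapse = ", "),
            "; using default radius ", attr(radii, "default"), " Angstrom")
    radius[is.na(radius)] <- attr(radii, "default")
  }

  atoms <- data.frame(
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    resid = resid,
    elety = trimws(as.character(at$elety)),
    elesy = elesy,
    x = as.numeric(at$x), y = as.numeric(at$y), z = as.numeric(at$z),
    radius = radius,
    hetero = at$type == "HETATM",
    stringsAsFactors = FALSE)
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in ", path)

  structure(list(atoms = atoms,
                 source_id = tools::file_path_sans_ext(basename(path)),
                 model_index = 1L),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model '", x$source_id, "': ", nrow(x$atoms), " atoms, ",
      length(unique(x$atoms$chain)), " chain(s)\n", sep = "")
  invisible(x)
}

.element_categories <- c("rprotein", "rRNA_domain", "tRNA", "mRNA",
                         "elongation_factor", "other")
.subunits <- c("30S", "50S", "none")

#' Construct an element map
#'
#' An element map defines the coarse-graining: each entry names one network
#' element (node) and assigns it a category, a subunit, a chain and a set of
#' inclusive author-numbered residue ranges (or `"all"` for the whole chain).
#'
#' @param entries List of entries; each a list with fields `name`,
#'   `category` (one of rprotein, rRNA_domain, tRNA, mRNA, elongation_factor,
#'   other), `subunit` (30S, 50S or none), `chain`, and `ranges` (either the
#'   string `"all"` or a list of length-2 integer vectors `c(lo, hi)`).
#' @return An `element_map` object.
#' @export
element_map <- function(entries) {
  stopifnot(is.list(entries), length(entries) > 0L)
  for (e in entries) {
    need <- c("name", "category", "subunit", "chain", "ranges")
    if (!all(need %in% names(e)))
      stop("element map entry missing field(s): ",
           paste(setdiff(need, names(e)), collapse = ", "))
    if (!e$category %in% .element_categories)
      stop("unknown category '", e$category, "' for element '", e$name, "'")
    if (!e$subunit %in% .subunits)
      stop("unknown subunit '", e$subunit, "' for element '", e$name, "'")
  }
  nm <- vapply(entries, `[[`, "", "name")
  if (anyDuplicated(nm))
    stop("duplicate element name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  # ranges of distinct elements must not overlap within one chain
  for (ch in unique(vapply(entries, `[[`, "", "chain"))) {
    idx <- which(vapply(entries, `[[`, "", "chain") == ch)
    if (length(idx) < 2L) next
    if (any(vapply(entries[idx], function(e) identical(e$ranges, "all"),
                   logical(1))))
      stop("chain ", ch, ": an 'all' entry cannot share the chain with ",
           "other elements")
    iv <- do.call(rbind, lapply(idx, function(i) {
      rg <- do.call(rbind, lapply(entries[[i]]$ranges, function(r)
        as.integer(r)))
      cbind(rg, i)
    }))
    o <- order(iv[, 1])
    iv <- iv[o, , drop = FALSE]
    if (nrow(iv) > 1L && any(iv[-1, 1] <= iv[-nrow(iv), 2]))
      stop("overlapping residue ranges in chain ", ch)
  }
  structure(list(entries = entries), class = "element_map")
}

#' Read an element map from a YAML file
#'
#' Expected schema: a top-level `elements:` list whose items carry `name`,
#' `category`, `subunit`, `chain` and `ranges` (either the string `all` or a
#' list of `[lo, hi]` pairs in author residue numbering). An example map is
#' shipped under `inst/extdata/`.
#'
#' @param path Path to a YAML file.
#' @return An `element_map`.
#' @export
read_element_map <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$elements)) stop("element map file lacks an 'elements:' key")
  entries <- lapply(y$elements, function(e) {
    if (is.null(e$ranges)) e$ranges <- "all"
    if (!identical(e$ranges, "all"))
      e$ranges <- lapply(e$ranges, as.integer)
    e
  })
  element_map(entries)
}

#' @export
print.element_map <- function(x, ...) {
  cat("element_map with", length(x$entries), "entries\n")
  invisible(x)
}

#' Coarse-grain a structure into named elements
#'
#' Applies an element map to a parsed structure: every map entry collects the
#' atoms of its chain whose author residue numbers fall in its ranges. Atoms
#' not covered by any entry are reported (message + `unmapped` attribute),
#' never silently dropped; entries referencing absent chains or matching no
#' atoms are omitted with a warning.
#'
#' @param model A `structure_model` from [parse_structure()].
#' @param emap An `element_map`.
#' @return List of `element` objects (fields `name`, `category`, `subunit`,
#'   `atoms`), with attribute `unmapped` holding the rows of unassigned atoms.
#' @export
assign_elements <- function(model, emap) {
  stopifnot(inherits(model, "structure_model"), inherits(emap, "element_map"))
  atoms <- model$atoms
  taken <- rep(FALSE, nrow(atoms))
  out <- list()
  for (e in emap$entries) {
    in_chain <- atoms$chain == e$chain
    if (!any(in_chain)) {
      warning("element '", e$name, "': chain '", e$chain,
              "' absent from structure; element omitted")
      next
    }
    sel <- if (identical(e$ranges, "all")) in_chain else {
      hit <- rep(FALSE, nrow(atoms))
      for (r in e$ranges)
        hit <- hit | (in_chain & atoms$resno >= r[1] & atoms$resno <= r[2])
      hit
    }
    if (!any(sel)) {
      warning("element '", e$name, "' matched no atoms; element omitted")
      next
    }
    taken <- taken | sel
    out[[e$name]] <- structure(
      list(name = e$name, category = e$category, subunit = e$subunit,
           atoms = atoms[sel, , drop = FALSE]),
      class = "element")
  }
  if (length(out) == 0L) stop("element map matched no atoms at all")
  unmapped <- atoms[!taken, , drop = FALSE]
  if (nrow(unmapped) > 0L)
    message(nrow(unmapped), " atom(s) not covered by the element map ",
            "(see attr(, 'unmapped'))")
  attr(out, "unmapped") <- unmapped
  out
}

#' @export
print.element <- function(x, ...) {
  cat("element '", x$name, "' (", x$category, ", ", x$subunit, "): ",
      nrow(x$atoms), " atoms\n", sep = "")
  invisible(x)
}

#' Write a structure model as a PDB file
#'
#' @param model A `structure_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = ifelse(a$hetero, "HETATM", "ATOM"),
                   resno = a$resno, resid = a$resid, chain = a$chain,
                   elety = a$elety, elesy = a$elesy)
  invisible(path)
}
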