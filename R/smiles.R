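#' Canonicalize SMILES notations
#'
#' Rewrites SMILES strings into the Open Babel canonical form so that
#' different notations of the same structure collapse to one string.
#' Stereochemistry markers (`@`, `/`, `\`) are removed by default, because the
#' models operate on two-dimensional structures and treat stereoisomers as
#' duplicates of their non-chiral form.
#'
#' @param smiles Character vector of SMILES notations.
#' @param strip_stereo Drop tetrahedral and cis/trans stereo markers before
#'   canonicalization (default `TRUE`).
#' @param ids Optional identifiers used in error messages; defaults to the
#'   input strings.
#' @return Character vector of canonical SMILES, same length as the input.
#' @examples
#' canonicalize_smiles(c("OC(=O)C(F)(F)F", "C(F)(F)(F)C(O)=O"))
#' @export
canonicalize_smiles <- function(smiles, strip_stereo = TRUE, ids = smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character(0))
  out <- vapply(seq_along(smiles), function(k) {
    s <- smiles[[k]]
    if (is.na(s) || !nzchar(s)) {
      stop("empty SMILES for input '", ids[[k]], "'")
    }
    if (strip_stereo) s <- .strip_stereo_markers(s)
    res <- suppressWarnings(
      ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\n"))
    )
    res <- sub("[\t\n ].*$", "", res)
    if (!nzchar(res)) {
      stop("unparseable SMILES for input '", ids[[k]], "': ", smiles[[k]])
    }
    res
  }, character(1))
  unname(out)
}

# Remove stereo bond markers and tetrahedral marks. "/" and "\" only ever
# denote double-bond geometry in SMILES; "@" only chirality inside brackets.
# "[C@@H]"-style atoms reduce to plain atoms when no other bracket content
# remains.
.strip_stereo_markers <- function(s) {
  s <- gsub("[/\\\\]", "", s)
  s <- gsub("@+", "", s)
  s <- gsub("\\[C([H]?)\\]", "C", s)
  s
}

#' Build a molecular graph from a SMILES notation
#'
#' Parses a SMILES string with Open Babel and returns the hydrogen-explicit
#' molecular graph used by the descriptor engine: atoms carry the element
#' symbol, formal charge and the three tabulated weighting properties
#' (mass, Sanderson electronegativity, polarizability); bonds carry the
#' conventional bond order, with aromatic bonds assigned order 1.5.
#'
#' @param smiles A single SMILES string.
#' @param explicit_h Make hydrogens explicit atoms (default `TRUE`).
#' @return An object of class `molgraph`: a list with data frames `atoms`
#'   (`element`, `charge`, `aromatic`, `mass`, `electronegativity`,
#'   `polarizability`) and `bonds` (`i`, `j`, `order`), plus the input
#'   `smiles` string.
#' @examples
#' g <- build_graph("FC(F)(F)F")
#' nrow(g$atoms)  # 5 atoms: 1 C + 4 F
#' @export
build_graph <- function(smiles, explicit_h = TRUE) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  txt <- suppressWarnings(
    if (explicit_h) {
      ChemmineOB::convertFormat("SMI", "MOL2", paste0(smiles, "\n"),
                                options = data.frame(names = "h", args = ""))
    } else {
      ChemmineOB::convertFormat("SMI", "MOL2", paste0(smiles, "\n"))
    }
  )
  if (!nzchar(txt) || !grepl("@<TRIPOS>ATOM", txt, fixed = TRUE)) {
    stop("unparseable SMILES: ", smiles)
  }
  g <- .parse_mol2(txt)
  bad <- setdiff(unique(g$atoms$element), element_properties()$element)
  if (length(bad) > 0) {
    # keep the graph usable for curation; property columns become NA
    g$atoms$mass <- g$atoms$electronegativity <- g$atoms$polarizability <- NA_real_
    known <- g$atoms$element %in% element_properties()$element
    if (any(known)) {
      g$atoms$mass[known] <- .element_property(g$atoms$element[known], "mass")
      g$atoms$electronegativity[known] <-
        .element_property(g$atoms$element[known], "electronegativity")
      g$atoms$polarizability[known] <-
        .element_property(g$atoms$element[known], "polarizability")
    }
  } else {
    g$atoms$mass <- .element_property(g$atoms$element, "mass")
    g$atoms$electronegativity <- .element_property(g$atoms$element, "electronegativity")
    g$atoms$polarizability <- .element_property(g$atoms$element, "polarizability")
  }
  g$smiles <- smiles
  class(g) <- "molgraph"
  g
}

# Minimal reader for the TRIPOS MOL2 blocks emitted by Open Babel. MOL2 is
# used (rather than SDF) because it is the one output format that preserves
# Open Babel's aromaticity perception ("ar" bond type) instead of a Kekule
# assignment. Formal charges are recovered from the SYBYL atom types where
# Open Babel encodes them (N.4, O.co2 are partial representations), so the
# charge column here is derived from the canonical SMILES instead.
.parse_mol2 <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  a0 <- grep("@<TRIPOS>ATOM", lines, fixed = TRUE)[1]
  b0 <- grep("@<TRIPOS>BOND", lines, fixed = TRUE)[1]
  end <- c(grep("^@<TRIPOS>", lines), length(lines) + 1L)
  a1 <- min(end[end > a0]) - 1L
  b1 <- min(end[end > b0]) - 1L
  atom_lines <- lines[(a0 + 1L):a1]
  atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
  af <- strsplit(trimws(atom_lines), "[[:space:]]+")
  sybyl <- vapply(af, `[[`, character(1), 6L)
  element <- sub("\\..*$", "", sybyl)
  # single-letter/two-letter element normalisation (MOL2 types are cased)
  element <- paste0(toupper(substr(element, 1, 1)),
                    tolower(substr(element, 2, nchar(element))))
  atoms <- data.frame(element = element,
                      aromatic = grepl("\\.ar$", sybyl),
                      charge = 0,
                      stringsAsFactors = FALSE)
  bonds <- data.frame(i = integer(0), j = integer(0), order = numeric(0))
  if (!is.na(b0) && b0 + 1L <= b1) {
    bond_lines <- lines[(b0 + 1L):b1]
    bond_lines <- bond_lines[nzchar(trimws(bond_lines))]
    if (length(bond_lines) > 0) {
      bf <- strsplit(trimws(bond_lines), "[[:space:]]+")
      otype <- vapply(bf, `[[`, character(1), 4L)
      order <- c("1" = 1, "2" = 2, "3" = 3, "ar" = 1.5, "am" = 1,
                 "du" = 1, "un" = 1)[otype]
      order[is.na(order)] <- 1
      bonds <- data.frame(
        i = as.integer(vapply(bf, `[[`, character(1), 2L)),
        j = as.integer(vapply(bf, `[[`, character(1), 3L)),
        order = as.numeric(order)
      )
    }
  }
  list(atoms = atoms, bonds = bonds)
}

#' @export
print.molgraph <- function(x, ...) {
  cat("Molecular graph:", x$smiles, "\n")
  cat(" ", nrow(x$atoms), "atoms,", nrow(x$bonds), "bonds\n")
  tab <- table(x$atoms$element)
  cat("  composition:", paste(names(tab), tab, sep = "", collapse = " "), "\n")
  invisible(x)
}

# Topological (graph) distance matrix of a molgraph; symmetric, zero diagonal,
# Inf for disconnected fragments. Optionally on the hydrogen-suppressed
# skeleton (returns the heavy-atom submatrix and the kept indices).
.topo_dist <- function(g, suppress_h = FALSE) {
  keep <- if (suppress_h) which(g$atoms$element != "H") else seq_len(nrow(g$atoms))
  if (length(keep) == 0) return(matrix(numeric(0), 0, 0))
  ig <- .as_igraph(g, keep)
  d <- igraph::distances(ig)
  dimnames(d) <- NULL
  attr(d, "kept") <- keep
  d
}

.as_igraph <- function(g, keep = seq_len(nrow(g$atoms))) {
  sel <- g$bonds$i %in% keep & g$bonds$j %in% keep
  remap <- match(seq_len(nrow(g$atoms)), keep)
  el <- cbind(remap[g$bonds$i[sel]], remap[g$bonds$j[sel]])
  ig <- igraph::make_empty_graph(n = length(keep), directed = FALSE)
  if (nrow(el) > 0) ig <- igraph::add_edges(ig, t(el))
  ig
}

# TRUE if the atom set (optionally H-suppressed) forms one connected component.
.is_connected_graph <- function(g) {
  ig <- .as_igraph(g)
  igraph::is_connected(ig)
}
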