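# Molecular-graph representation of C/H carbocations with explicit hydrogens.
#
# A cation_graph stores every atom (hydrogens included) because the reaction
# operators edit individual H atoms: the reactive-atom exclusion rule and the
# hydride/proton moves reference them directly. The compact carbon-skeleton
# form used by the C++ engine (implicit H, derived from valence) is an
# internal encoding; conversions are lossless for C/H species.

#' Construct a carbocation molecular graph
#'
#' Builds an explicit-hydrogen molecular graph of a C/H species with an
#' optional trivalent cationic carbon. Validity is enforced on construction:
#' the graph must be connected; every H has exactly one single bond; every C
#' has total bond order at most 4 (exactly 3 at the charge site, which may
#' not participate in a double bond); double bonds join two carbons.
#'
#' @param atoms Character vector of element symbols, `"C"` or `"H"`.
#' @param bonds Integer matrix with columns `i`, `j`, `order` (1 or 2), one
#'   row per bond, indices into `atoms`.
#' @param charge_site Index of the cationic carbon, or `NA` for a neutral
#'   species.
#' @param coords Optional numeric matrix (`length(atoms)` x 3) of Cartesian
#'   coordinates in Angstrom; present only in geometric mode.
#' @param stereo_tags Optional per-atom parity labels; present only when
#'   stereochemistry handling is enabled.
#' @return An object of class `cation_graph`.
#' @seealso [parse_smiles()], [canonical_key()], [cation_formula()]
#' @export
cation_graph <- function(atoms, bonds, charge_site = NA_integer_,
                         coords = NULL, stereo_tags = NULL) {
  atoms <- as.character(atoms)
  if (!all(atoms %in% c("C", "H")))
    stop("only C and H atoms are supported")
  bonds <- matrix(as.integer(bonds), ncol = 3,
                  dimnames = list(NULL, c("i", "j", "order")))
  charge_site <- as.integer(charge_site)
  g <- structure(
    list(atoms = atoms, bonds = bonds, charge_site = charge_site,
         coords = coords, stereo_tags = stereo_tags),
    class = "cation_graph"
  )
  validate_cation_graph(g)
  g
}

#' @export
print.cation_graph <- function(x, ...) {
  f <- cation_formula(x)
  cat(sprintf("<cation_graph> C%dH%d%s  %s\n", f[["nC"]], f[["nH"]],
              if (f[["charge"]] > 0) "+" else "",
              canonical_key(x)))
  invisible(x)
}

# bond-order lookup as a dense matrix over all atoms (H included)
bond_matrix <- function(g) {
  n <- length(g$atoms)
  bo <- matrix(0L, n, n)
  if (nrow(g$bonds)) {
    bo[g$bonds[, 1:2, drop = FALSE]] <- g$bonds[, 3]
    bo[g$bonds[, 2:1, drop = FALSE]] <- g$bonds[, 3]
  }
  bo
}

atom_valence <- function(g) {
  n <- length(g$atoms)
  v <- integer(n)
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      v[g$bonds[k, 1]] <- v[g$bonds[k, 1]] + g$bonds[k, 3]
      v[g$bonds[k, 2]] <- v[g$bonds[k, 2]] + g$bonds[k, 3]
    }
  }
  v
}

validate_cation_graph <- function(g) {
  n <- length(g$atoms)
  if (n < 1) stop("empty molecule")
  b <- g$bonds
  if (nrow(b)) {
    if (any(b[, 1:2] < 1 | b[, 1:2] > n)) stop("bond index out of range")
    if (any(b[, 1] == b[, 2])) stop("self bond")
    if (any(!b[, 3] %in% 1:2)) stop("bond order must be 1 or 2")
    pair <- paste(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2]))
    if (anyDuplicated(pair)) stop("duplicate bond")
  }
  v <- atom_valence(g)
  isH <- g$atoms == "H"
  if (any(v[isH] != 1)) stop("every H must have exactly one single bond")
  if (nrow(b) && any(b[, 3] == 2 & (isH[b[, 1]] | isH[b[, 2]])))
    stop("H cannot be in a double bond")
  cs <- g$charge_site
  if (!is.na(cs)) {
    if (cs < 1 || cs > n || g$atoms[cs] != "H" && g$atoms[cs] != "C")
      stop("charge_site out of range")
    if (g$atoms[cs] != "C") stop("charge_site must be a carbon")
    if (v[cs] != 3) stop("cationic carbon must have total bond order 3")
    if (nrow(b) && any(b[, 3] == 2 & (b[, 1] == cs | b[, 2] == cs)))
      stop("cationic carbon cannot be in a double bond")
  }
  if (any(v[!isH] > 4)) stop("carbon valence exceeded")
  full <- ifelse(isH, 1L, ifelse(seq_len(n) == ifelse(is.na(cs), 0L, cs), 3L, 4L))
  if (any(v != full))
    stop("unfilled valence: hydrogens must be explicit")
  # connectivity
  if (n > 1) {
    seen <- logical(n); seen[1] <- TRUE; queue <- 1L
    bo <- bond_matrix(g)
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      nb <- which(bo[u, ] > 0 & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    if (!all(seen)) stop("molecular graph is disconnected")
  }
  invisible(g)
}

# ---------------------------------------------------------------------------
# conversions between the explicit-H graph and the implicit-H engine encoding
# ---------------------------------------------------------------------------

# engine encoding: list(n, charge (1-based, 0 = neutral), bo = n x n matrix)
# over carbons only, in the order the carbons appear in g$atoms
as_heavy <- function(g) {
  cidx <- which(g$atoms == "C")
  n <- length(cidx)
  pos <- integer(length(g$atoms))
  pos[cidx] <- seq_len(n)
  bo <- matrix(0L, n, n)
  b <- g$bonds
  if (nrow(b)) {
    cc <- g$atoms[b[, 1]] == "C" & g$atoms[b[, 2]] == "C"
    for (k in which(cc)) {
      i <- pos[b[k, 1]]; j <- pos[b[k, 2]]
      bo[i, j] <- bo[j, i] <- b[k, 3]
    }
  }
  chg <- if (is.na(g$charge_site)) 0L else pos[g$charge_site]
  list(n = n, charge = chg, bo = bo)
}

# materialize explicit hydrogens from the engine encoding
heavy_to_graph <- function(mol) {
  n <- mol$n
  chg <- mol$charge
  cap <- rep(4L, n)
  if (chg > 0) cap[chg] <- 3L
  hs <- cap - rowSums(mol$bo)
  atoms <- c(rep("C", n), rep("H", sum(hs)))
  bonds <- which(upper.tri(mol$bo) & mol$bo > 0, arr.ind = TRUE)
  blist <- cbind(bonds, mol$bo[bonds])
  hat <- n
  for (i in seq_len(n)) {
    if (hs[i] > 0)
      for (k in seq_len(hs[i])) {
        hat <- hat + 1L
        blist <- rbind(blist, c(i, hat, 1L))
      }
  }
  cation_graph(atoms, blist, charge_site = if (chg > 0) chg else NA_integer_)
}

# ---------------------------------------------------------------------------
# SMILES
# ---------------------------------------------------------------------------

#' Parse a SMILES string into a cation graph
#'
#' Accepts the C/H subset of SMILES: aliphatic `C`, bracket atoms such as
#' `[CH2+]`, `[C+]`, or `[H]`, single and double bonds, branches, ring
#' closures (including `%nn`), and directional bond symbols `/` and `\`
#' (read as single bonds; configurational information is not retained in
#' constitutional mode). Implicit hydrogens are materialized as explicit
#' graph atoms.
#'
#' @param text A SMILES string describing a species with only C and H atoms
#'   and at most one +1 formal charge.
#' @return A [cation_graph()].
#' @examples
#' g <- parse_smiles("CC(C)=CCC/C(C)=C/[CH2+]")  # geranyl cation
#' cation_formula(g)
#' @export
parse_smiles <- function(text) {
  if (!is.character(text) || length(text) != 1 || !nzchar(text))
    stop("text must be a single non-empty SMILES string")
  chars <- strsplit(text, "")[[1]]
  atoms <- character(0)      # element per parsed heavy/bracket atom
  hexp <- integer(0)         # explicit H count from bracket atoms (-1 = implicit)
  charge <- integer(0)       # formal charge per atom
  bonds <- matrix(integer(0), 0, 3)
  stack <- integer(0)
  prev <- 0L
  pending <- 1L              # bond order to use for the next connection
  ring <- list()             # open ring closures: digit -> c(atom, order)
  i <- 1L
  add_atom <- function(el, nh, q) {
    atoms[[length(atoms) + 1L]] <<- el
    hexp[[length(hexp) + 1L]] <<- nh
    charge[[length(charge) + 1L]] <<- q
    a <- length(atoms)
    if (prev > 0L)
      bonds <<- rbind(bonds, c(prev, a, pending))
    prev <<- a
    pending <<- 1L
  }
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "C") {
      add_atom("C", -1L, 0L)
    } else if (ch == "[") {
      j <- i
      while (j <= length(chars) && chars[j] != "]") j <- j + 1L
      if (j > length(chars)) stop("malformed SMILES: unclosed bracket")
      body <- paste(chars[(i + 1):(j - 1)], collapse = "")
      m <- regmatches(body, regexec("^(C|H)(H([0-9]*))?([+-][0-9]*)?$", body))[[1]]
      if (length(m) == 0) stop("malformed or unsupported bracket atom: [", body, "]")
      el <- m[2]
      nh <- if (nzchar(m[3])) { if (nzchar(m[4])) as.integer(m[4]) else 1L } else 0L
      q <- 0L
      if (nzchar(m[5])) {
        sign <- if (substr(m[5], 1, 1) == "+") 1L else -1L
        mag <- if (nchar(m[5]) > 1) as.integer(substr(m[5], 2, nchar(m[5]))) else 1L
        q <- sign * mag
      }
      if (el == "H" && nh > 0) stop("malformed bracket atom: [", body, "]")
      add_atom(el, nh, q)
      i <- j
    } else if (ch == "=") {
      pending <- 2L
    } else if (ch %in% c("-", "/", "\\")) {
      pending <- 1L
    } else if (ch == "#") {
      stop("triple bonds are not supported")
    } else if (ch == "(") {
      if (prev == 0L) stop("malformed SMILES: branch before any atom")
      stack <- c(stack, prev)
    } else if (ch == ")") {
      if (!length(stack)) stop("malformed SMILES: unbalanced parentheses")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        d <- paste(chars[(i + 1):(i + 2)], collapse = "")
        i <- i + 2L
      } else d <- ch
      if (prev == 0L) stop("malformed SMILES: ring closure before any atom")
      if (is.null(ring[[d]])) {
        ring[[d]] <- c(prev, pending)
      } else {
        open <- ring[[d]]
        ord <- max(open[2], pending) # bond symbol may sit at either end
        if (open[1] == prev) stop("malformed SMILES: ring bond to self")
        bonds <- rbind(bonds, c(open[1], prev, ord))
        ring[[d]] <- NULL
      }
      pending <- 1L
    } else if (ch == ".") {
      stop("disconnected structures are not supported")
    } else if (grepl("[a-z]", ch)) {
      stop("aromatic or unsupported atoms are not supported")
    } else {
      stop("unsupported element or character in SMILES: '", ch, "'")
    }
    i <- i + 1L
  }
  if (length(stack)) stop("malformed SMILES: unbalanced parentheses")
  if (length(Filter(Negate(is.null), ring))) stop("malformed SMILES: unclosed ring bond")
  if (!length(atoms)) stop("malformed SMILES: no atoms")
  if (any(charge < 0)) stop("anions are not supported")
  if (any(charge > 1)) stop("multiply charged atoms are not supported")
  if (sum(charge) > 1) stop("at most one charged atom is supported")
  cs <- which(charge == 1L)
  if (length(cs) && atoms[cs] != "C") stop("the charge must sit on a carbon")

  # materialize hydrogens: explicit bracket counts, or fill valence for bare C
  valence <- integer(length(atoms))
  if (nrow(bonds))
    for (k in seq_len(nrow(bonds))) {
      valence[bonds[k, 1]] <- valence[bonds[k, 1]] + bonds[k, 3]
      valence[bonds[k, 2]] <- valence[bonds[k, 2]] + bonds[k, 3]
    }
  full_atoms <- atoms
  full_bonds <- bonds
  for (a in seq_along(atoms)) {
    if (atoms[a] != "C") next
    target <- if (length(cs) && a == cs) 3L else 4L
    nh <- if (hexp[a] >= 0) hexp[a] else target - valence[a]
    if (nh < 0 || valence[a] + nh != target)
      stop("valence error at atom ", a, if (length(cs) && a == cs)
        " (cationic carbon must have 3 bonds)" else "")
    if (nh > 0)
      for (k in seq_len(nh)) {
        full_atoms <- c(full_atoms, "H")
        full_bonds <- rbind(full_bonds, c(a, length(full_atoms), 1L))
      }
  }
  cation_graph(full_atoms, full_bonds,
               charge_site = if (length(cs)) cs else NA_integer_)
}

#' Canonical SMILES key of a species
#'
#' Computes a permutation-invariant canonical SMILES string: two graphs have
#' equal keys if and only if they are the same constitutional isomer.
#' Canonicalization runs on the carbon skeleton (hydrogen counts are implied
#' by valence) using colour refinement with individualization on ties,
#' minimizing a serialized adjacency code.
#'
#' @param g A [cation_graph()].
#' @param use_stereo If `TRUE` and `g` carries `stereo_tags`, the per-atom
#'   parities (in canonical atom order) are appended to the key so that
#'   configurational isomers separate. The default (`FALSE`) erases
#'   stereochemistry: the package's constitutional mode deliberately
#'   collapses stereoisomers, since skeleton- and route-level results do not
#'   depend on configuration.
#' @return A single character string.
#' @examples
#' canonical_key(parse_smiles("[CH2+]C=C")) == canonical_key(parse_smiles("C=C[CH2+]"))
#' @export
canonical_key <- function(g, use_stereo = FALSE) {
  stopifnot(inherits(g, "cation_graph"))
  res <- cpp_canon(as_heavy(g))
  key <- res$smiles
  if (isTRUE(use_stereo) && !is.null(g$stereo_tags)) {
    cidx <- which(g$atoms == "C")
    tags <- g$stereo_tags[cidx][res$order]
    tags[is.na(tags)] <- "."
    key <- paste0(key, "|", paste(tags, collapse = ""))
  }
  key
}

#' Render a cation graph as canonical SMILES
#'
#' @param g A [cation_graph()].
#' @return The canonical SMILES string (equal to [canonical_key()] in
#'   constitutional mode).
#' @export
render_smiles <- function(g) canonical_key(g)

#' Element counts of a species
#'
#' @param g A [cation_graph()].
#' @return Named integer vector with elements `nC`, `nH` and `charge`
#'   (0 or 1).
#' @examples
#' cation_formula(parse_smiles("C[C+](C)C"))  # c(nC = 4, nH = 9, charge = 1)
#' @export
cation_formula <- function(g) {
  stopifnot(inherits(g, "cation_graph"))
  c(nC = sum(g$atoms == "C"), nH = sum(g$atoms == "H"),
    charge = if (is.na(g$charge_site)) 0L else 1L)
}

#' Classify a carbocation by substitution and allylic character
#'
#' Primary, secondary, or tertiary by the carbon-neighbour count of the
#' charge site (1, 2, 3); the `allylic_` prefix is added when a C=C double
#' bond is adjacent to the charge site (the delocalized allyl system).
#'
#' @param g A charged [cation_graph()].
#' @return One of `"primary"`, `"secondary"`, `"tertiary"`,
#'   `"allylic_primary"`, `"allylic_secondary"`, `"allylic_tertiary"`.
#' @examples
#' classify_cation(parse_smiles("C[C+](C)C"))   # tertiary
#' classify_cation(parse_smiles("[CH2+]CC"))    # primary
#' @export
classify_cation <- function(g) {
  stopifnot(inherits(g, "cation_graph"))
  if (is.na(g$charge_site)) stop("neutral species has no cation class")
  class_label(cpp_classify(as_heavy(g)))
}

class_label <- function(code) {
  base <- c("primary", "secondary", "tertiary")[code %% 10]
  ifelse(code >= 10, paste0("allylic_", base), base)
}

#' Allylic resonance forms of a cation
#'
#' For each C=C double bond adjacent to the charge site, emits the
#' allylically shifted form: the charge moves to the far alkene carbon and
#' the double bond moves next to the old charge site. The input itself is
#' included; results are deduplicated by canonical key.
#'
#' @param g A charged [cation_graph()].
#' @return A named list of [cation_graph()] objects keyed by canonical
#'   SMILES (length 1 when no adjacent alkene exists or the shift is
#'   degenerate by symmetry).
#' @examples
#' length(resonance_forms(parse_smiles("[CH2+]C=C")))  # 1: allyl is symmetric
#' @export
resonance_forms <- function(g) {
  stopifnot(inherits(g, "cation_graph"))
  if (is.na(g$charge_site)) stop("neutral species has no resonance forms")
  out <- list()
  out[[canonical_key(g)]] <- g
  queue <- list(as_heavy(g))
  while (length(queue)) {
    m <- queue[[1]]; queue <- queue[-1]
    for (p in cpp_expand(m, REACTION_TYPES[["RESONANCE"]], -1L)) {
      key <- cpp_canon(p$mol)$smiles
      if (is.null(out[[key]])) {
        out[[key]] <- heavy_to_graph(p$mol)
        queue <- c(queue, list(p$mol))
      }
    }
  }
  out
}
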