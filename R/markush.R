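#' Define a Markush structure
#'
#' A Markush structure is a scaffold with labelled attachment positions plus,
#' for each position, a list of substituent fragments. It implicitly defines
#' a combinatorial library whose theoretical size is the product of the
#' per-position fragment counts.
#'
#' Conventions (standard R-group SMILES):
#' * the scaffold marks each attachment position with a numbered dummy atom
#'   `[*:1]`, `[*:2]`, ...; each dummy must be written directly after its
#'   neighbour atom, either as a branch (`c1ccc([*:1])cc1`) or terminally
#'   (`CCN[*:2]`);
#' * each fragment has exactly one attachment point, written as a leading
#'   dummy atom (`*`, `[*]` or `[*:n]`), e.g. `*CC(=O)N` — the atom following
#'   the dummy is bonded to the scaffold neighbour by a single bond.
#'
#' @param scaffold scaffold SMILES with `P >= 1` numbered dummy atoms.
#' @param fragment_sets list of `P` non-empty character vectors of fragment
#'   SMILES, in position order (position `p` fills `[*:p]`).
#' @param position_labels optional position names; default `R1 ... RP`.
#' @return an object of class `markush_definition`.
#' @examples
#' \donttest{
#' md <- markush_definition("c1ccc([*:1])cc1", list(c("*C", "*CC", "*O")))
#' md
#' }
#' @seealso [enumerate_library()], [read_markush()]
#' @export
markush_definition <- function(scaffold, fragment_sets, position_labels = NULL) {
  .check(is.character(scaffold) && length(scaffold) == 1L && nzchar(scaffold),
         "scaffold must be a single non-empty SMILES string")
  .check(is.list(fragment_sets) && length(fragment_sets) >= 1L,
         "fragment_sets must be a non-empty list of character vectors")
  P <- length(fragment_sets)
  for (p in seq_len(P)) {
    fs <- fragment_sets[[p]]
    .check(is.character(fs) && length(fs) >= 1L && all(nzchar(fs)),
           "fragment list at position %d must be a non-empty character vector", p)
  }
  # scaffold dummies: [*:1] .. [*:P], each unique, branch or terminal
  for (p in seq_len(P)) {
    tok <- sprintf("[*:%d]", p)
    hits <- gregexpr(tok, scaffold, fixed = TRUE)[[1]]
    .check(length(hits) == 1L && hits[1] > 1L,
           "scaffold must contain exactly one '%s' attachment point, not at the start of the SMILES", tok)
    after <- hits[1] + nchar(tok)
    nxt <- substr(scaffold, after, after)
    .check(nxt == "" || nxt == ")",
           "attachment point '%s' must be written as a branch '([*:%d])' or terminally; found '%s' after it",
           tok, p, nxt)
  }
  # fragment dummies: exactly one, leading
  for (p in seq_len(P)) {
    for (i in seq_along(fragment_sets[[p]])) {
      f <- fragment_sets[[p]][i]
      ndum <- .count_dummies(f)
      .check(ndum == 1L,
             "fragment %d at position %d ('%s') must contain exactly one attachment dummy atom (found %d)",
             i, p, f, ndum)
      .check(grepl("^(\\[\\*(:[0-9]+)?\\]|\\*)", f),
             "fragment %d at position %d ('%s') must start with its attachment dummy atom",
             i, p, f)
    }
  }
  if (is.null(position_labels)) position_labels <- paste0("R", seq_len(P))
  .check(length(position_labels) == P && !anyDuplicated(position_labels),
         "position_labels must be %d unique names", P)
  # chemical parseability of every fragment (dummy atoms parse fine)
  for (p in seq_len(P)) {
    can <- canonical_smiles(fragment_sets[[p]])
    bad <- which(is.na(can))
    .check(length(bad) == 0L,
           "unparseable fragment at position %d, index %d: '%s'",
           p, bad[1], fragment_sets[[p]][bad[1]])
  }
  structure(list(scaffold = scaffold,
                 fragment_sets = fragment_sets,
                 position_labels = position_labels),
            class = "markush_definition")
}

# number of attachment dummies ('*' atoms) in a SMILES string
.count_dummies <- function(s) {
  length(gregexpr("\\[\\*(:[0-9]+)?\\]|\\*", s)[[1]][
    gregexpr("\\[\\*(:[0-9]+)?\\]|\\*", s)[[1]] > 0])
}

# Strip the leading dummy atom of a fragment, keeping any explicit bond
# symbol that follows it.
.fragment_body <- function(frag) {
  sub("^(\\[\\*(:[0-9]+)?\\]|\\*)", "", frag)
}

# Remap ring-closure labels of a SMILES fragment into the %{base}..%99 range
# so that splicing into a scaffold cannot collide with the scaffold's own
# (or a sibling fragment's) open ring bonds. Ring-closure tokens appear
# outside square brackets only, as a single digit or as %nn.
.remap_rings <- function(s, base) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  out <- character(0)
  map <- integer(0)
  new_label <- function(key) {
    if (is.na(map[key])) {
      map[key] <<- base + length(map[!is.na(map)])
      .check(map[key] <= 99L, "too many ring closures while splicing fragment '%s'", s)
    }
    sprintf("%%%d", map[key])
  }
  map <- rep(NA_integer_, 100L)
  i <- 1L
  inb <- FALSE
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") inb <- TRUE
    if (ch == "]") inb <- FALSE
    if (!inb && ch == "%") {
      key <- as.integer(paste0(chars[i + 1L], chars[i + 2L])) + 1L
      out <- c(out, new_label(key))
      i <- i + 3L
    } else if (!inb && grepl("[0-9]", ch)) {
      out <- c(out, new_label(as.integer(ch) + 1L))
      i <- i + 1L
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  paste(out, collapse = "")
}

#' Enumerate the full combinatorial library of a Markush definition
#'
#' Forms the cross product of the per-position fragment lists: each product
#' bonds every fragment's attachment atom to its scaffold position with a
#' single bond. Products are canonicalized and deduplicated (distinct
#' fragment tuples can yield the same molecule, e.g. on symmetric
#' scaffolds); the first-encountered provenance tuple is kept.
#'
#' @param defn a [markush_definition()].
#' @param cap refuse to enumerate if the theoretical size exceeds this
#'   (default `1e6`); large Markush spaces should be reduced first, e.g. to
#'   the explicitly listed substituents.
#' @param canonicalize canonicalize and deduplicate via Open Babel (default
#'   `TRUE`). With `FALSE` the raw spliced SMILES are kept (fast preview).
#' @param name library name used in ids (default `"MCL"`).
#' @return a `compound_library`: list with `members` (data.frame of `id`,
#'   `smiles`, and one `r<p>_idx` provenance column per position), `name`,
#'   `chemistry = "smiles"`, and the definition.
#' @examples
#' \donttest{
#' md <- markush_definition("O=C(N([*:2])C)c1ccc([*:1])cc1",
#'                          list(c("*F", "*Cl"), c("*C", "*CC", "*CCC")))
#' lib <- enumerate_library(md)
#' lib$members
#' }
#' @export
enumerate_library <- function(defn, cap = 1e6, canonicalize = TRUE,
                              name = "MCL") {
  .check(inherits(defn, "markush_definition"), "defn must be a markush_definition")
  sizes <- vapply(defn$fragment_sets, length, integer(1))
  theo <- prod(sizes)
  .check(theo <= cap,
         "theoretical library size %s exceeds the enumeration cap %s; reduce the fragment lists or raise `cap`",
         format(theo, big.mark = ","), format(cap, big.mark = ","))
  P <- length(sizes)
  idx <- as.matrix(expand.grid(lapply(sizes, seq_len), KEEP.OUT.ATTRS = FALSE))
  colnames(idx) <- paste0("r", seq_len(P), "_idx")

  # pre-splice: remapped fragment bodies per position
  bodies <- vector("list", P)
  for (p in seq_len(P)) {
    base <- 40L + 15L * (p - 1L)
    bodies[[p]] <- vapply(defn$fragment_sets[[p]],
                          function(f) .remap_rings(.fragment_body(f), base),
                          character(1), USE.NAMES = FALSE)
  }
  smi <- rep(defn$scaffold, nrow(idx))
  for (p in seq_len(P)) {
    tok <- sprintf("[*:%d]", p)
    # sub() is per-element; token occurs exactly once by construction
    smi <- mapply(function(s, b) sub(tok, b, s, fixed = TRUE),
                  smi, bodies[[p]][idx[, p]], USE.NAMES = FALSE)
  }

  if (canonicalize) {
    can <- canonical_smiles(smi)
    bad <- which(is.na(can))
    if (length(bad)) {
      warning(sprintf("%d of %d enumerated products failed to parse and were dropped",
                      length(bad), length(can)))
      can <- can[-bad]
      idx <- idx[-bad, , drop = FALSE]
    }
    keep <- !duplicated(can)
    smi <- can[keep]
    idx <- idx[keep, , drop = FALSE]
  }
  members <- data.frame(id = sprintf("%s-%06d", name, seq_along(smi)),
                        smiles = smi, stringsAsFactors = FALSE)
  members <- cbind(members, as.data.frame(idx))
  rownames(members) <- NULL
  structure(list(members = members, name = name, chemistry = "smiles",
                 n_positions = P, definition = defn),
            class = "compound_library")
}

# internal: cross-product library over abstract fragment indices (no
# chemistry); structure key is the dot-joined index tuple, unique by
# construction. fragment_ids: list of per-position integer vectors giving
# the identity of each fragment in a parent frame (for BCL remapping).
.enumerate_abstract <- function(fragment_ids, name = "MCL") {
  P <- length(fragment_ids)
  idx <- as.matrix(expand.grid(fragment_ids, KEEP.OUT.ATTRS = FALSE))
  colnames(idx) <- paste0("r", seq_len(P), "_idx")
  key <- apply(idx, 1L, paste, collapse = ".")
  members <- data.frame(id = sprintf("%s-%06d", name, seq_len(nrow(idx))),
                        smiles = key, stringsAsFactors = FALSE)
  members <- cbind(members, as.data.frame(idx))
  rownames(members) <- NULL
  structure(list(members = members, name = name, chemistry = "abstract",
                 n_positions = P, definition = NULL),
            class = "compound_library")
}

#' Library size
#' @param lib a `compound_library`.
#' @return number of (deduplicated) member compounds.
#' @export
library_size <- function(lib) {
  .check(inherits(lib, "compound_library"), "not a compound_library")
  nrow(lib$members)
}

# provenance tuples as an integer matrix N x P
.provenance <- function(lib) {
  cols <- grep("^r[0-9]+_idx$", names(lib$members), value = TRUE)
  .check(length(cols) > 0L,
         "library '%s' carries no fragment provenance", lib$name)
  as.matrix(lib$members[, cols, drop = FALSE])
}

#' @export
print.compound_library <- function(x, ...) {
  cat(sprintf("Compound library '%s': %d members, %d substituent position(s) [%s]\n",
              x$name, nrow(x$members), x$n_positions, x$chemistry))
  if (nrow(x$members)) {
    print(utils::head(x$members, 4L))
    if (nrow(x$members) > 4L) cat(sprintf("  ... %d more\n", nrow(x$members) - 4L))
  }
  invisible(x)
}

#' Declare a subset of a library
#'
#' Declares e.g. the bibliographical compounds (BD) as a subset of a parent
#' library, by member index, member id, or structure (canonical-SMILES
#' lookup).
#'
#' @param library parent `compound_library`.
#' @param member_ids integer indices into the parent members, or character
#'   member ids.
#' @param smiles alternatively, SMILES of the subset compounds; resolved by
#'   canonical-structure lookup in the parent.
#' @param name subset name (default `"BD"`).
#' @return a `subset_declaration` with unique, in-range `member_ids`.
#' @export
subset_declaration <- function(library, member_ids = NULL, smiles = NULL,
                               name = "BD") {
  .check(inherits(library, "compound_library"), "library must be a compound_library")
  N <- nrow(library$members)
  if (!is.null(smiles)) {
    .check(is.null(member_ids), "give member_ids or smiles, not both")
    can <- canonical_smiles(smiles)
    member_ids <- match(can, library$members$smiles)
    miss <- which(is.na(member_ids))
    .check(length(miss) == 0L,
           "%d subset structure(s) not found in library '%s' (first offender: '%s')",
           length(miss), library$name, smiles[miss[1]])
  } else if (is.character(member_ids)) {
    ids <- match(member_ids, library$members$id)
    .check(!anyNA(ids), "unknown member id(s): %s",
           paste(utils::head(member_ids[is.na(ids)], 3L), collapse = ", "))
    member_ids <- ids
  }
  member_ids <- as.integer(member_ids)
  .check(length(member_ids) >= 1L, "subset must be non-empty")
  .check(!anyNA(member_ids) && all(member_ids >= 1L & member_ids <= N),
         "member indices must lie in 1..%d", N)
  .check(!anyDuplicated(member_ids), "member indices must be unique")
  structure(list(library_ref = library$name, member_ids = member_ids,
                 name = name),
            class = "subset_declaration")
}

#' @export
print.subset_declaration <- function(x, ...) {
  cat(sprintf("Subset '%s' of library '%s': %d member(s)\n",
              x$name, x$library_ref, length(x$member_ids)))
  invisible(x)
}

#' Recombine the fragments of a subset into its combinatorial library
#'
#' Collects, per position, the set of fragments used by the subset members
#' and enumerates their full cross product — the "bibliographic
#' combinatorial library" (BCL) of a set of reported compounds: the
#' combinatorial space spanned by substituents that have actually been made.
#' The result is a sub-library of the parent (every provenance tuple draws
#' from the parent's fragment sets) and contains the subset.
#'
#' @param parent the parent `compound_library` (with fragment provenance).
#' @param subset a [subset_declaration()] or integer member indices.
#' @param name name of the recombined library (default `"BCL"`).
#' @param cap enumeration cap passed through to [enumerate_library()].
#' @return a `compound_library` with provenance indices in the parent's
#'   fragment numbering.
#' @export
recombine_fragments <- function(parent, subset, name = "BCL", cap = 1e6) {
  .check(inherits(parent, "compound_library"), "parent must be a compound_library")
  if (!inherits(subset, "subset_declaration"))
    subset <- subset_declaration(parent, member_ids = subset, name = "subset")
  prov <- .provenance(parent)
  P <- ncol(prov)
  used <- lapply(seq_len(P), function(p) sort(unique(prov[subset$member_ids, p])))
  if (parent$chemistry == "abstract" || is.null(parent$definition)) {
    .check(parent$chemistry == "abstract",
           "parent library has no Markush definition attached; cannot recombine")
    return(.enumerate_abstract(used, name = name))
  }
  defn <- parent$definition
  sub_defn <- markush_definition(defn$scaffold,
                                 lapply(seq_len(P), function(p)
                                   defn$fragment_sets[[p]][used[[p]]]),
                                 defn$position_labels)
  lib <- enumerate_library(sub_defn, cap = cap, name = name)
  # remap provenance back to the parent's fragment numbering
  for (p in seq_len(P)) {
    col <- sprintf("r%d_idx", p)
    lib$members[[col]] <- used[[p]][lib$members[[col]]]
  }
  lib$definition <- defn
  lib
}
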