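#' Compute an open 1D/2D molecular descriptor matrix
#'
#' Calculates a dense set of one- and two-dimensional descriptors for every
#' library compound: Open Babel physicochemical descriptors (MW, logP,
#' TPSA, molar refractivity, H-bond donors/acceptors, rotatable bonds),
#' bond-order counts, ring count (cyclomatic number), aromatic-bond
#' fraction, per-element atom counts and heteroatom fraction. Compounds for
#' which calculation fails are excluded with a warning.
#'
#' The descriptor list is recorded in the result so downstream projection of
#' new compounds uses the identical column set.
#'
#' @param library a `compound_library` with SMILES chemistry, or a character
#'   vector of SMILES.
#' @param ids compound ids (defaults to library member ids).
#' @return a `descriptor_matrix`: list with `values` (N x D numeric matrix,
#'   rownames = compound ids), `descriptor_names`, `compound_ids`, `set`.
#' @seealso [chem_space()], [read_descriptors()]
#' @export
compute_descriptors <- function(library, ids = NULL) {
  if (inherits(library, "compound_library")) {
    .check(library$chemistry == "smiles",
           "library '%s' is abstract (no structures); its descriptors come from the scenario generator",
           library$name)
    smiles <- library$members$smiles
    if (is.null(ids)) ids <- library$members$id
  } else {
    smiles <- as.character(library)
    if (is.null(ids)) ids <- sprintf("CPD-%06d", seq_along(smiles))
  }
  .check(length(smiles) > 0L, "no compounds to describe")
  raw <- .obabel_descriptors(smiles)
  elem <- .parse_formula(raw$formula)
  vals <- cbind(as.matrix(raw[, .OB_NUMERIC]), elem)
  # derived 2D features
  vals <- cbind(vals,
                n_rings = raw$bonds - raw$atoms + 1,
                arom_bond_frac = ifelse(raw$bonds > 0, raw$abonds / raw$bonds, 0),
                hetero_frac = ifelse(raw$atoms > 0, (raw$atoms - elem[, "nC"]) / raw$atoms, 0))
  ok <- stats::complete.cases(vals)
  if (any(!ok))
    warning(sprintf("descriptor calculation failed for %d compound(s); excluded: %s",
                    sum(!ok), paste(utils::head(ids[!ok], 3L), collapse = ", ")))
  vals <- vals[ok, , drop = FALSE]
  rownames(vals) <- ids[ok]
  structure(list(values = vals,
                 descriptor_names = colnames(vals),
                 compound_ids = ids[ok],
                 set = "openbabel_open2d"),
            class = "descriptor_matrix")
}

#' Construct a descriptor matrix from a plain numeric matrix
#'
#' For precomputed or synthetic descriptor sets.
#'
#' @param values numeric matrix, one row per compound.
#' @param compound_ids,descriptor_names optional dimnames.
#' @param set label recorded as the descriptor-set name.
#' @return a `descriptor_matrix`.
#' @export
descriptor_matrix <- function(values, compound_ids = NULL,
                              descriptor_names = NULL, set = "custom") {
  values <- as.matrix(values)
  .check(is.numeric(values) && nrow(values) > 0L && ncol(values) > 0L,
         "values must be a non-empty numeric matrix")
  .check(!anyNA(values), "descriptor matrix must not contain missing values")
  if (is.null(compound_ids))
    compound_ids <- rownames(values) %||% sprintf("CPD-%06d", seq_len(nrow(values)))
  if (is.null(descriptor_names))
    descriptor_names <- colnames(values) %||% sprintf("D%03d", seq_len(ncol(values)))
  dimnames(values) <- list(compound_ids, descriptor_names)
  structure(list(values = values, descriptor_names = descriptor_names,
                 compound_ids = compound_ids, set = set),
            class = "descriptor_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a descriptor matrix as CSV
#'
#' First column `id`, remaining columns numeric descriptors.
#'
#' @param path CSV file.
#' @return [read_descriptors()]: a `descriptor_matrix`.
#' @export
read_descriptors <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  .check("id" %in% names(df), "descriptor CSV must have an 'id' column: %s", path)
  vals <- as.matrix(df[, setdiff(names(df), "id"), drop = FALSE])
  descriptor_matrix(vals, compound_ids = as.character(df$id), set = "csv")
}

#' @rdname read_descriptors
#' @param desc a `descriptor_matrix`.
#' @export
write_descriptors <- function(desc, path) {
  .check(inherits(desc, "descriptor_matrix"), "desc must be a descriptor_matrix")
  df <- data.frame(id = desc$compound_ids, desc$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat(sprintf("Descriptor matrix [%s]: %d compounds x %d descriptors\n",
              x$set, nrow(x$values), ncol(x$values)))
  invisible(x)
}
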