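# Library and Markush-definition file I/O.
#
# Formats: .smi (whitespace-separated: smiles, id, then one provenance
# column per position), .csv (id, smiles, r1_idx...), .sdf (V2000; id as
# title, provenance as SD tags). Markush definitions: YAML or JSON with a
# scaffold string and per-position fragment lists.

.guess_format <- function(path, format = c("auto", "smi", "sdf", "csv")) {
  format <- match.arg(format)
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         smi = "smi", smiles = "smi",
         sdf = "sdf", sd = "sdf", mol = "sdf",
         csv = "csv",
         stop(sprintf("cannot infer library format from extension '.%s'", ext),
              call. = FALSE))
}

#' Write a compound library to disk
#'
#' @param lib a `compound_library`.
#' @param path output file; extension selects the format unless `format`
#'   is given.
#' @param format `"smi"`, `"sdf"`, `"csv"` or `"auto"` (from extension).
#' @return `path`, invisibly.
#' @seealso [read_library()]
#' @export
write_library <- function(lib, path, format = "auto") {
  .check(inherits(lib, "compound_library"), "lib must be a compound_library")
  format <- .guess_format(path, format)
  m <- lib$members
  prov_cols <- grep("^r[0-9]+_idx$", names(m), value = TRUE)
  if (format == "smi") {
    writeLines(do.call(paste, c(list(m$smiles, m$id), m[prov_cols])), path)
  } else if (format == "csv") {
    utils::write.csv(m, path, row.names = FALSE, quote = FALSE)
  } else {
    .check(lib$chemistry == "smiles", "abstract libraries cannot be written as SDF")
    fin <- tempfile(fileext = ".smi")
    on.exit(unlink(fin), add = TRUE)
    writeLines(paste(m$smiles, m$id), fin)
    suppressWarnings(system2(.obabel(),
                             c(shQuote(fin), "-osdf", "-O", shQuote(path), "--gen2D"),
                             stdout = FALSE, stderr = FALSE))
    # append provenance as SD tags
    sdf <- ChemmineR::read.SDFset(path)
    blocks <- lapply(seq_len(nrow(m)), function(i) {
      v <- as.character(unlist(m[i, prov_cols]))
      names(v) <- prov_cols
      v
    })
    ChemmineR::datablock(sdf) <- blocks
    ChemmineR::write.SDF(sdf, file = path)
  }
  invisible(path)
}

#' Read a compound library from disk
#'
#' Malformed records are skipped with a warning reporting the final count.
#'
#' @param path input file (`.smi`, `.sdf`, `.csv`).
#' @param format see [write_library()].
#' @param name library name (default: file name without extension).
#' @param canonicalize re-canonicalize structures on read (default `TRUE`).
#' @return a `compound_library`.
#' @export
read_library <- function(path, format = "auto", name = NULL,
                         canonicalize = TRUE) {
  .check(file.exists(path), "no such file: %s", path)
  format <- .guess_format(path, format)
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  if (format == "smi") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "[ \t]+")
    smi <- vapply(parts, `[[`, character(1), 1L)
    id <- vapply(parts, function(p) if (length(p) >= 2L) p[2] else NA_character_,
                 character(1))
    id[is.na(id)] <- sprintf("%s-%06d", name, which(is.na(id)))
    extra <- lapply(parts, function(p) suppressWarnings(as.integer(p[-(1:2)])))
    P <- max(c(0L, lengths(extra)))
    members <- data.frame(id = id, smiles = smi, stringsAsFactors = FALSE)
    if (P > 0L && all(lengths(extra) == P)) {
      prov <- do.call(rbind, extra)
      colnames(prov) <- paste0("r", seq_len(P), "_idx")
      members <- cbind(members, as.data.frame(prov))
    } else P <- 0L
  } else if (format == "csv") {
    members <- utils::read.csv(path, stringsAsFactors = FALSE)
    .check(all(c("id", "smiles") %in% names(members)),
           "CSV library must have 'id' and 'smiles' columns: %s", path)
    P <- length(grep("^r[0-9]+_idx$", names(members)))
  } else {
    sdf <- suppressWarnings(ChemmineR::read.SDFset(path))
    ok <- ChemmineR::validSDF(sdf)
    if (any(!ok))
      warning(sprintf("skipped %d malformed SDF record(s) in %s; %d kept",
                      sum(!ok), path, sum(ok)))
    sdf <- sdf[ok]
    fout <- tempfile(fileext = ".smi")
    on.exit(unlink(fout), add = TRUE)
    # structures via obabel (robust, fast); ids and tags via ChemmineR
    tmp <- tempfile(fileext = ".sdf")
    on.exit(unlink(tmp), add = TRUE)
    ChemmineR::write.SDF(sdf, file = tmp)
    suppressWarnings(system2(.obabel(),
                             c(shQuote(tmp), "-osmi", "-O", shQuote(fout), "-xc", "-xn"),
                             stdout = FALSE, stderr = FALSE))
    smi <- readLines(fout, warn = FALSE)
    smi <- trimws(smi[nzchar(smi)])
    .check(length(smi) == length(sdf),
           "obabel returned %d structures for %d SDF records in %s",
           length(smi), length(sdf), path)
    id <- unname(vapply(ChemmineR::SDFset2list(sdf),
                        function(x) x$header[["Molecule_Name"]], character(1)))
    id[!nzchar(id)] <- sprintf("%s-%06d", name, which(!nzchar(id)))
    members <- data.frame(id = id, smiles = smi, stringsAsFactors = FALSE)
    db <- ChemmineR::datablock(sdf)
    tags <- unique(unlist(lapply(db, names)))
    prov_tags <- grep("^r[0-9]+_idx$", tags, value = TRUE)
    P <- length(prov_tags)
    for (tag in prov_tags)
      members[[tag]] <- vapply(db, function(d)
        suppressWarnings(as.integer(d[[tag]])), integer(1))
  }
  if (canonicalize && nrow(members)) {
    can <- canonical_smiles(members$smiles)
    bad <- which(is.na(can))
    if (length(bad)) {
      warning(sprintf("skipped %d unparseable record(s) in %s; %d kept",
                      length(bad), path, nrow(members) - length(bad)))
      members <- members[-bad, , drop = FALSE]
      can <- can[-bad]
    }
    members$smiles <- can
  }
  rownames(members) <- NULL
  structure(list(members = members, name = name, chemistry = "smiles",
                 n_positions = length(grep("^r[0-9]+_idx$", names(members))),
                 definition = NULL),
            class = "compound_library")
}

#' Read / write a Markush definition (YAML or JSON)
#'
#' The file holds `scaffold` (SMILES with `[*:n]` attachment points),
#' `fragment_sets` (list of per-position SMILES lists) and optionally
#' `position_labels`.
#'
#' @param path file path; `.yml`/`.yaml` or `.json`.
#' @return [read_markush()]: a `markush_definition`.
#' @export
read_markush <- function(path) {
  .check(file.exists(path), "no such file: %s", path)
  ext <- tolower(tools::file_ext(path))
  obj <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  .check(!is.null(obj$scaffold) && !is.null(obj$fragment_sets),
         "%s must define 'scaffold' and 'fragment_sets'", path)
  fs <- lapply(obj$fragment_sets, as.character)
  markush_definition(obj$scaffold, fs, obj$position_labels)
}

#' @rdname read_markush
#' @param defn a `markush_definition`.
#' @export
write_markush <- function(defn, path) {
  .check(inherits(defn, "markush_definition"), "defn must be a markush_definition")
  obj <- list(scaffold = defn$scaffold,
              fragment_sets = defn$fragment_sets,
              position_labels = defn$position_labels)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) yaml::write_yaml(obj, path)
  else jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
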