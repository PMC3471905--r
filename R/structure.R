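#' Coarse-grained Calpha structures
#'
#' An `en_structure` is a tibble with one row per residue bead and columns
#' `residue_id` (author numbering, strictly increasing), `x`, `y`, `z`
#' (Calpha position, Angstrom), `chain` and `subdomain` (one of
#' `"S1".."S4"` or `NA`). It is the reference geometry from which elastic
#' networks are built: the bead positions define both the network topology
#' and the zero-energy state.
#'
#' @param residue_id integer vector of residue numbers, strictly increasing.
#' @param coords numeric matrix (n x 3) of Calpha positions in Angstrom.
#' @param chain single chain label.
#' @param subdomain optional character vector of subdomain labels
#'   (`"S1".."S4"` or `NA`).
#' @param source free-text provenance string.
#' @return A tibble of class `en_structure`.
#' @export
en_structure <- function(residue_id, coords, chain = "A", subdomain = NULL,
                         source = "") {
  residue_id <- as.integer(residue_id)
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L || nrow(coords) != length(residue_id)) {
    stop("`coords` must be an n x 3 matrix with one row per residue", call. = FALSE)
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite", call. = FALSE)
  if (length(residue_id) > 1L && any(diff(residue_id) <= 0L)) {
    stop("`residue_id` must be strictly increasing (one bead per residue)",
         call. = FALSE)
  }
  if (is.null(subdomain)) subdomain <- rep(NA_character_, length(residue_id))
  s <- tibble::tibble(
    residue_id = residue_id,
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    chain = as.character(chain),
    subdomain = as.character(subdomain)
  )
  class(s) <- c("en_structure", class(s))
  attr(s, "source") <- source
  s
}

#' @export
print.en_structure <- function(x, ...) {
  cat(sprintf("# en_structure: %d beads, chain %s%s\n", nrow(x),
              paste(unique(x$chain), collapse = ","),
              if (nzchar(attr(x, "source") %||% "")) {
                paste0(" [", attr(x, "source"), "]")
              } else ""))
  NextMethod()
}

#' Extract bead coordinates as a matrix
#'
#' @param s an `en_structure`.
#' @return n x 3 numeric matrix.
#' @export
coords_matrix <- function(s) {
  m <- cbind(s$x, s$y, s$z)
  colnames(m) <- c("x", "y", "z")
  m
}

#' Read Calpha coordinates from a structure file
#'
#' Reads a PDB or mmCIF file, keeps one Calpha bead per resolved residue of
#' the selected chain (ordered by residue number), collapses alternate
#' locations to the highest-occupancy one, and skips residues lacking a
#' Calpha with a warning. HETATM records are ignored at this layer; ligand
#' geometry enters only through [add_adp()] / [add_atp()]. Insertion codes
#' are rejected so that residue-id arithmetic stays unambiguous.
#'
#' @param path path to a `.pdb` or `.cif` file.
#' @param chain chain identifier to extract.
#' @return An [en_structure()].
#' @export
load_ca_structure <- function(path, chain = "A") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif")) {
    bio3d::read.cif(path, verbose = FALSE)
  } else {
    # keep alternate locations; they are collapsed by occupancy below
    bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  }
  atoms <- pdb$atom
  atoms <- atoms[atoms$type == "ATOM" & atoms$chain %in% chain, , drop = FALSE]
  if (nrow(atoms) == 0L) stop("chain '", chain, "' not found in ", path, call. = FALSE)
  ins <- atoms$insert
  if (any(!is.na(ins) & nzchar(ins))) {
    stop("insertion codes present in chain '", chain,
         "'; renumber the file before use", call. = FALSE)
  }
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) stop("no Calpha atoms in chain '", chain, "'", call. = FALSE)
  # collapse altlocs: keep highest occupancy per residue number
  if (anyDuplicated(ca$resno)) {
    occ <- ifelse(is.na(ca$o), 1, ca$o)
    ca <- ca[order(ca$resno, -occ), , drop = FALSE]
    ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  }
  ca <- ca[order(ca$resno), , drop = FALSE]
  n_res <- length(unique(atoms$resno))
  if (nrow(ca) < n_res) {
    warning(sprintf("%d residue(s) in chain '%s' lack a Calpha and were skipped",
                    n_res - nrow(ca), chain), call. = FALSE)
  }
  en_structure(ca$resno, cbind(ca$x, ca$y, ca$z), chain = chain,
               source = basename(path))
}

#' Subdomain schemes
#'
#' A subdomain scheme maps residue-number intervals to the four canonical
#' labels `S1..S4`. `actin_subdomains()` returns the standard actin
#' assignment: S1 = 1-32, 70-144, 338-372; S2 = 33-69; S3 = 145-180,
#' 270-337; S4 = 181-269 (S1+S2 form the outer domain, S3+S4 the inner
#' domain). `read_subdomain_scheme()` reads the same shape from a YAML or
#' JSON file whose top level maps each label to a list of two-element
#' `[from, to]` intervals.
#'
#' @return A named list of interval lists, one entry per subdomain label.
#' @export
actin_subdomains <- function() {
  list(
    S1 = list(c(1L, 32L), c(70L, 144L), c(338L, 372L)),
    S2 = list(c(33L, 69L)),
    S3 = list(c(145L, 180L), c(270L, 337L)),
    S4 = list(c(181L, 269L))
  )
}

#' @rdname actin_subdomains
#' @param path YAML or JSON file with one `[from, to]` interval list per label.
#' @export
read_subdomain_scheme <- function(path) {
  raw <- if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  lapply(raw, function(iv) {
    if (is.matrix(iv)) iv <- split(iv, seq_len(nrow(iv)))
    if (!is.list(iv)) iv <- list(iv)
    lapply(iv, function(v) as.integer(v[1:2]))
  })
}

scheme_ids <- function(scheme) {
  lapply(scheme, function(iv) {
    unlist(lapply(iv, function(v) seq.int(v[1], v[2])))
  })
}

#' Assign subdomain labels to a structure
#'
#' Labels each residue by membership in the scheme's inclusive residue-number
#' intervals; residues outside every interval get `NA` ("none"). Assignment
#' is a pure function of the residue id. Overlapping intervals across labels
#' are an error; scheme residues absent from the structure are allowed and
#' reported via a message.
#'
#' @param s an [en_structure()].
#' @param scheme a subdomain scheme, see [actin_subdomains()].
#' @return The structure with its `subdomain` column populated.
#' @export
assign_subdomains <- function(s, scheme = actin_subdomains()) {
  ids <- scheme_ids(scheme)
  all_ids <- unlist(ids, use.names = FALSE)
  if (anyDuplicated(all_ids)) {
    stop("subdomain intervals overlap across labels", call. = FALSE)
  }
  lab <- rep(NA_character_, nrow(s))
  for (nm in names(ids)) lab[s$residue_id %in% ids[[nm]]] <- nm
  missing <- setdiff(all_ids, s$residue_id)
  if (length(missing) > 0L) {
    message(length(missing), " scheme residue id(s) absent from the structure")
  }
  s$subdomain <- lab
  s
}

#' Write conformations to a multi-model PDB or XYZ file
#'
#' Each frame becomes one MODEL (PDB) or one block (XYZ); coordinates are
#' written to 3 decimals in Angstrom, so a round trip through
#' [read_conformations()] agrees within 1e-3 per coordinate.
#'
#' @param frames a single n x 3 matrix or a list of them, one per frame.
#' @param s the [en_structure()] supplying residue ids and the chain label.
#' @param path output file; extension `.xyz` selects XYZ, anything else PDB.
#' @return `path`, invisibly.
#' @export
write_conformations <- function(frames, s, path) {
  if (is.matrix(frames)) frames <- list(frames)
  n <- nrow(s)
  ok <- vapply(frames, function(f) is.matrix(f) && nrow(f) == n && ncol(f) == 3L,
               logical(1))
  if (!all(ok)) {
    stop("every frame must be an n x 3 matrix matching the structure (n = ",
         n, ")", call. = FALSE)
  }
  if (tolower(tools::file_ext(path)) == "xyz") {
    con <- file(path, "w")
    on.exit(close(con))
    for (f in frames) {
      writeLines(c(as.character(n), "frame"), con)
      writeLines(sprintf("CA %.3f %.3f %.3f", f[, 1], f[, 2], f[, 3]), con)
    }
  } else {
    xyz <- do.call(rbind, lapply(frames, function(f) as.vector(t(f))))
    bio3d::write.pdb(file = path, xyz = xyz, resno = s$residue_id,
                     resid = rep("ALA", n), elety = rep("CA", n),
                     chain = s$chain)
  }
  invisible(path)
}

#' Read frames back from a multi-model PDB or XYZ file
#'
#' @param path file written by [write_conformations()].
#' @return A list of n x 3 coordinate matrices, one per frame.
#' @export
read_conformations <- function(path) {
  if (tolower(tools::file_ext(path)) == "xyz") {
    lines <- readLines(path)
    frames <- list()
    i <- 1L
    while (i <= length(lines)) {
      n <- as.integer(lines[i])
      block <- lines[(i + 2L):(i + 1L + n)]
      m <- do.call(rbind, lapply(strsplit(block, "\\s+"), function(p) {
        as.numeric(p[2:4])
      }))
      frames[[length(frames) + 1L]] <- m
      i <- i + 2L + n
    }
    frames
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    lapply(seq_len(nrow(xyz)), function(k) {
      matrix(xyz[k, ], ncol = 3L, byrow = TRUE)
    })
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
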