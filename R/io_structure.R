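# Structure file I/O: CIF (small-molecule, loop-based subset), VASP
# POSCAR, and extended XYZ with Lattice= cell records.

#' Read a crystal structure file
#'
#' Supported dialects: \code{cif} (the plain loop-based small-molecule
#' subset: cell parameters plus an _atom_site_ loop with fractional
#' coordinates), \code{poscar} (VASP 5 style with an element-symbol line;
#' Direct or Cartesian coordinates), and \code{xyz} (a single extended-XYZ
#' frame whose comment line carries \code{Lattice="ax ay az bx ... cz"}).
#'
#' @param path file path.
#' @param dialect one of "cif", "poscar", "xyz"; default guesses from the
#'   file extension.
#' @param molecules optional molecular partition passed to
#'   \code{\link{crystal}}.
#' @return a \code{\link{crystal}}.
#' @export
read_structure <- function(path, dialect = c("auto", "cif", "poscar", "xyz"),
                           molecules = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext, cif = "cif", xyz = "xyz",
                      vasp = "poscar", poscar = "poscar",
                      stop("cannot guess dialect from extension '", ext, "'"))
  }
  switch(dialect,
         cif = read_cif(path, molecules),
         poscar = read_poscar(path, molecules),
         xyz = {
           fr <- read_xyz_frames(path, max_frames = 1)[[1]]
           crystal(fr$cell, fr$elements, cart_to_frac(fr$cart, fr$cell),
                   molecules = molecules, provenance = path)
         })
}

read_cif <- function(path, molecules = NULL) {
  lines <- readLines(path, warn = FALSE)
  strip <- function(x) sub("#.*$", "", x)
  num <- function(key) {
    hit <- grep(paste0("^\\s*", key, "\\b"), lines)
    if (length(hit) == 0) stop("CIF parse error: missing ", key, " in ", path)
    val <- strsplit(trimws(strip(lines[hit[1]])), "\\s+")[[1]][2]
    as.numeric(sub("\\(.*\\)", "", val))  # drop e.s.d. parentheses
  }
  cellp <- c(num("_cell_length_a"), num("_cell_length_b"),
             num("_cell_length_c"), num("_cell_angle_alpha"),
             num("_cell_angle_beta"), num("_cell_angle_gamma"))
  # locate the atom_site loop
  loop_starts <- grep("^\\s*loop_", lines)
  for (ls in loop_starts) {
    i <- ls + 1
    tags <- character(0)
    while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
      tags <- c(tags, trimws(lines[i])); i <- i + 1
    }
    if (!any(grepl("^_atom_site_fract_x", tags))) next
    col <- function(pat) {
      j <- grep(pat, tags)
      if (length(j) == 0) NA_integer_ else j[1]
    }
    cx <- col("^_atom_site_fract_x"); cy <- col("^_atom_site_fract_y")
    cz <- col("^_atom_site_fract_z")
    cel <- col("^_atom_site_type_symbol")
    if (is.na(cel)) cel <- col("^_atom_site_label")
    rows <- list()
    while (i <= length(lines)) {
      ln <- trimws(strip(lines[i]))
      if (ln == "" || grepl("^(loop_|_|data_)", ln)) break
      rows[[length(rows) + 1]] <- strsplit(ln, "\\s+")[[1]]
      i <- i + 1
    }
    if (length(rows) == 0) stop("CIF parse error: empty atom_site loop near line ", ls)
    getnum <- function(v) as.numeric(sub("\\(.*\\)", "", v))
    elements <- vapply(rows, function(r) sub("[0-9].*$", "", r[cel]), "")
    frac <- t(vapply(rows, function(r) getnum(r[c(cx, cy, cz)]), numeric(3)))
    return(crystal(cellp, elements, frac, molecules = molecules,
                   provenance = path))
  }
  stop("CIF parse error: no _atom_site_ loop found in ", path)
}

read_poscar <- function(path, molecules = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 8) stop("POSCAR parse error: file too short: ", path)
  scale <- as.numeric(trimws(lines[2]))
  cell <- t(vapply(3:5, function(i) {
    v <- as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]])
    if (length(v) != 3 || anyNA(v)) stop("POSCAR parse error at line ", i)
    v
  }, numeric(3))) * scale
  symbols <- strsplit(trimws(lines[6]), "\\s+")[[1]]
  counts <- as.integer(strsplit(trimws(lines[7]), "\\s+")[[1]])
  if (anyNA(counts)) stop("POSCAR parse error: expected counts at line 7")
  i <- 8
  if (grepl("^[Ss]", trimws(lines[i]))) i <- i + 1  # selective dynamics
  mode <- trimws(lines[i]); i <- i + 1
  n <- sum(counts)
  coords <- t(vapply(seq_len(n), function(k) {
    as.numeric(strsplit(trimws(lines[i + k - 1]), "\\s+")[[1]][1:3])
  }, numeric(3)))
  elements <- rep(symbols, counts)
  frac <- if (grepl("^[DdFf]", mode)) coords else cart_to_frac(coords, cell)
  crystal(cell, elements, frac, molecules = molecules, provenance = path)
}

#' Write a crystal structure file
#'
#' @param crystal a \code{\link{crystal}}.
#' @param path output path.
#' @param dialect "cif", "poscar" or "xyz".
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(crystal, path, dialect = c("cif", "poscar", "xyz")) {
  dialect <- match.arg(dialect)
  p <- cell_parameters(crystal$cell)
  lines <- switch(dialect,
    cif = c(
      "data_cryspec",
      sprintf("_cell_length_a    %.8f", p[1]),
      sprintf("_cell_length_b    %.8f", p[2]),
      sprintf("_cell_length_c    %.8f", p[3]),
      sprintf("_cell_angle_alpha %.8f", p[4]),
      sprintf("_cell_angle_beta  %.8f", p[5]),
      sprintf("_cell_angle_gamma %.8f", p[6]),
      "_symmetry_space_group_name_H-M 'P 1'",
      "loop_",
      "_atom_site_label",
      "_atom_site_type_symbol",
      "_atom_site_fract_x",
      "_atom_site_fract_y",
      "_atom_site_fract_z",
      sprintf("%s%d %s %.10f %.10f %.10f",
              crystal$elements, seq_along(crystal$elements),
              crystal$elements,
              crystal$frac[, 1], crystal$frac[, 2], crystal$frac[, 3])),
    poscar = {
      # write in canonical axis orientation; symbols grouped in blocks
      ord <- order(match(crystal$elements, unique(crystal$elements)))
      cellm <- cell_matrix(p[1], p[2], p[3], p[4], p[5], p[6])
      syms <- unique(crystal$elements)
      counts <- as.integer(table(factor(crystal$elements, levels = syms)))
      c("cryspec structure", "1.0",
        apply(cellm, 1, function(v) sprintf("  %.10f %.10f %.10f", v[1], v[2], v[3])),
        paste(syms, collapse = " "),
        paste(counts, collapse = " "),
        "Direct",
        sprintf("  %.10f %.10f %.10f",
                crystal$frac[ord, 1], crystal$frac[ord, 2], crystal$frac[ord, 3]))
    },
    xyz = {
      cart <- frac_to_cart(crystal$frac, crystal$cell)
      lat <- paste(sprintf("%.10f", as.vector(t(crystal$cell))), collapse = " ")
      c(sprintf("%d", n_sites(crystal)),
        sprintf('Lattice="%s" Properties=species:S:1:pos:R:3', lat),
        sprintf("%-2s %16.10f %16.10f %16.10f",
                crystal$elements, cart[, 1], cart[, 2], cart[, 3]))
    })
  writeLines(lines, path)
  invisible(path)
}

parse_xyz_comment <- function(comment) {
  # key=value pairs; values may be quoted strings with spaces
  out <- list()
  pat <- '([A-Za-z_][A-Za-z0-9_]*)=("([^"]*)"|\\S+)'
  m <- gregexpr(pat, comment, perl = TRUE)[[1]]
  if (m[1] == -1) return(out)
  starts <- as.integer(m); lens <- attr(m, "match.length")
  for (k in seq_along(starts)) {
    kv <- substr(comment, starts[k], starts[k] + lens[k] - 1)
    eq <- regexpr("=", kv)
    key <- substr(kv, 1, eq - 1)
    val <- substr(kv, eq + 1, nchar(kv))
    val <- gsub('^"|"$', "", val)
    out[[key]] <- val
  }
  out
}

#' Read an extended-XYZ trajectory
#'
#' Each frame is \code{n}, a comment line with \code{Lattice="..."} and
#' optional \code{Time=} (fs) and \code{Dipole="Mx My Mz"} (e Angstrom)
#' records, then \code{n} lines of \code{element x y z} in cartesian
#' Angstrom.
#'
#' @param path file path.
#' @param max_frames optional cap on the number of frames read.
#' @return list of frames; each frame has \code{cell}, \code{elements},
#'   \code{cart}, and optionally \code{time} and \code{dipole}.
#' @export
read_xyz_frames <- function(path, max_frames = Inf) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1
  while (i <= length(lines) && length(frames) < max_frames) {
    if (trimws(lines[i]) == "") { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("XYZ parse error: expected atom count at line ", i)
    meta <- parse_xyz_comment(lines[i + 1])
    if (is.null(meta$Lattice)) stop("XYZ parse error: no Lattice= record at line ", i + 1)
    lat <- as.numeric(strsplit(trimws(meta$Lattice), "\\s+")[[1]])
    cell <- matrix(lat, 3, 3, byrow = TRUE)
    body <- lines[(i + 2):(i + 1 + n)]
    toks <- strsplit(trimws(body), "\\s+")
    elements <- vapply(toks, `[`, "", 1)
    cart <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    fr <- list(cell = cell, elements = elements, cart = cart)
    if (!is.null(meta$Time)) fr$time <- as.numeric(meta$Time)
    if (!is.null(meta$Dipole)) {
      fr$dipole <- as.numeric(strsplit(trimws(meta$Dipole), "\\s+")[[1]])
    }
    frames[[length(frames) + 1]] <- fr
    i <- i + 2 + n
  }
  frames
}

#' Write an extended-XYZ trajectory
#'
#' @param frames list of frames as returned by \code{\link{read_xyz_frames}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_xyz_frames <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    lat <- paste(sprintf("%.10f", as.vector(t(fr$cell))), collapse = " ")
    extra <- ""
    if (!is.null(fr$time)) extra <- paste0(extra, sprintf(' Time=%.6f', fr$time))
    if (!is.null(fr$dipole)) {
      extra <- paste0(extra, sprintf(' Dipole="%.10g %.10g %.10g"',
                                     fr$dipole[1], fr$dipole[2], fr$dipole[3]))
    }
    writeLines(c(
      sprintf("%d", nrow(fr$cart)),
      sprintf('Lattice="%s" Properties=species:S:1:pos:R:3%s', lat, extra),
      sprintf("%-2s %16.10f %16.10f %16.10f",
              fr$elements, fr$cart[, 1], fr$cart[, 2], fr$cart[, 3])), con)
  }
  invisible(path)
}
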