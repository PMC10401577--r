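# Plain-text numeric array I/O in the layout produced by common phonon
# post-processing chains: a header line with the dimension, then row-major
# whitespace-separated numbers.

#' Read/write a force-constant matrix
#'
#' Layout: one header line with 3N, then 3N rows of 3N numbers
#' (eV/Angstrom^2), row-major per-site 3x3 blocks.
#'
#' @param path file path.
#' @return 3N x 3N matrix.
#' @export
read_force_constants <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n3 <- as.integer(trimws(lines[1]))
  vals <- as.numeric(unlist(strsplit(trimws(lines[-1]), "\\s+")))
  if (length(vals) != n3 * n3) stop("force-constant file has wrong size")
  matrix(vals, n3, n3, byrow = TRUE)
}

#' @rdname read_force_constants
#' @param fc matrix to write.
#' @export
write_force_constants <- function(fc, path) {
  writeLines(c(sprintf("%d", nrow(fc)),
               apply(fc, 1, function(r) paste(sprintf("%.12g", r), collapse = " "))),
             path)
  invisible(path)
}

#' Read/write Born effective charges
#'
#' Layout: a header line with N, then 3 rows of 3 per atom (e units).
#'
#' @param path file path.
#' @return 3 x 3 x N array.
#' @export
read_born_charges <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[1]))
  vals <- as.numeric(unlist(strsplit(trimws(lines[-1]), "\\s+")))
  if (length(vals) != 9 * n) stop("Born-charge file has wrong size")
  out <- array(0, c(3, 3, n))
  for (a in seq_len(n)) {
    out[, , a] <- matrix(vals[(a - 1) * 9 + 1:9], 3, 3, byrow = TRUE)
  }
  out
}

#' @rdname read_born_charges
#' @param born 3 x 3 x N array to write.
#' @export
write_born_charges <- function(born, path) {
  n <- dim(born)[3]
  body <- unlist(lapply(seq_len(n), function(a) {
    apply(born[, , a], 1, function(r) paste(sprintf("%.12g", r), collapse = " "))
  }))
  writeLines(c(sprintf("%d", n), body), path)
  invisible(path)
}

#' Write a phonon mode table as CSV
#'
#' Columns: mode index, wavenumber (cm^-1, negative = imaginary-flagged),
#' powder-average IR oscillator strength (trace/3 of the strength tensor, 0
#' when no Born charges are available), and the translational / rotational /
#' internal percentages when a crystal is supplied.
#'
#' @param modes a \code{\link{gamma_phonons}} result.
#' @param path output CSV path.
#' @param crystal optional \code{\link{crystal}} for the rigid-body
#'   decomposition columns.
#' @param volume cell volume in Angstrom^3 (needed for strengths; defaults
#'   to the crystal's volume).
#' @return \code{path}, invisibly.
#' @export
write_mode_table <- function(modes, path, crystal = NULL, volume = NULL) {
  nm <- length(modes$frequency)
  df <- data.frame(mode = seq_len(nm),
                   wavenumber_cm1 = ifelse(modes$imaginary, -1, 1) * modes$frequency,
                   acoustic = modes$acoustic)
  if (!is.null(modes$born)) {
    if (is.null(volume)) {
      if (is.null(crystal)) stop("need a crystal or an explicit volume for strengths")
      volume <- cell_volume(crystal$cell)
    }
    S <- mode_intensities(modes, volume)
    df$ir_strength <- vapply(seq_len(nm), function(k) {
      sum(diag(S[, , k])) / 3
    }, numeric(1))
  }
  if (!is.null(crystal)) {
    dec <- decompose_modes(modes, crystal)
    df$pct_translational <- dec$translational
    df$pct_rotational <- dec$rotational
    df$pct_internal <- dec$internal
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
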