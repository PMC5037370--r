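#' Per-post traction force field of a single cell
#'
#' Holds the 2D traction force vectors a cell exerts on the posts of a
#' micropost array, together with the cell's polarization axis.
#'
#' @param x_um,y_um Post positions, um.
#' @param fx_nN,fy_nN Force components, nN, finite.
#' @param axis Length-2 polarization axis; normalized to unit length
#'   (zero-length axis errors).
#' @return A `cell_force_field` object (data.frame with an `axis`
#'   attribute).
#' @export
cell_force_field <- function(x_um, y_um, fx_nN, fy_nN, axis = c(1, 0)) {
  n <- length(fx_nN)
  if (n < 1) stop("force field must contain at least one vector",
                  call. = FALSE)
  if (length(fy_nN) != n || length(x_um) != n || length(y_um) != n)
    stop("field columns must have equal length", call. = FALSE)
  if (!all(is.finite(c(x_um, y_um, fx_nN, fy_nN))))
    stop("field entries must be finite", call. = FALSE)
  if (length(axis) != 2 || !all(is.finite(axis)))
    stop("axis must be a finite length-2 vector", call. = FALSE)
  nr <- sqrt(sum(axis^2))
  if (nr == 0) stop("polarization axis must have nonzero length",
                    call. = FALSE)
  f <- data.frame(post_id = seq_len(n), x_um = x_um, y_um = y_um,
                  fx_nN = fx_nN, fy_nN = fy_nN)
  attr(f, "axis") <- axis / nr
  class(f) <- c("cell_force_field", "data.frame")
  f
}

#' Total cellular force: sum of per-post force magnitudes
#'
#' `F = sum_i |F_i|` over the posts (Euclidean norms), the scalar measure of
#' a cell's overall contractile state. Magnitudes add regardless of
#' direction, so the result is invariant under rigid rotation of the frame.
#'
#' @param field A `cell_force_field`.
#' @return Total force, nN.
#' @export
total_cell_force <- function(field) {
  stopifnot(inherits(field, "cell_force_field"))
  sum(sqrt(field$fx_nN^2 + field$fy_nN^2))
}

#' Summed force magnitudes parallel and perpendicular to the polarization axis
#'
#' Projects each post force onto the cell's unit polarization axis and its
#' normal and sums absolute components: `F_par = sum_i |F_i . a|`,
#' `F_perp = sum_i |F_i . a_perp|`. Each is bounded above by the total
#' force, and both are invariant under joint rotation of field and axis.
#'
#' @param field A `cell_force_field` (its `axis` attribute is used).
#' @return Named numeric vector `c(F_parallel =, F_perp =)`, nN.
#' @export
polarized_force_components <- function(field) {
  stopifnot(inherits(field, "cell_force_field"))
  a <- attr(field, "axis")
  perp <- c(-a[2], a[1])
  c(F_parallel = sum(abs(field$fx_nN * a[1] + field$fy_nN * a[2])),
    F_perp = sum(abs(field$fx_nN * perp[1] + field$fy_nN * perp[2])))
}

#' Write a cell force field as delimited text
#'
#' Dialect: comma-separated header `post_id,x_um,y_um,fx_nN,fy_nN`, 12
#' significant digits. The polarization axis travels separately (config).
#'
#' @param field A `cell_force_field`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_force_field <- function(field, path) {
  stopifnot(inherits(field, "cell_force_field"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("post_id,x_um,y_um,fx_nN,fy_nN", con, sep = "\n")
  fmt <- function(v) formatC(v, digits = 12, format = "g")
  writeLines(paste(field$post_id, fmt(field$x_um), fmt(field$y_um),
                   fmt(field$fx_nN), fmt(field$fy_nN), sep = ","),
             con, sep = "\n")
  invisible(path)
}

#' Read a cell force field from delimited text
#'
#' @param path File path (dialect of [write_cell_force_field()]).
#' @param axis Polarization axis to attach (default x).
#' @return A `cell_force_field`.
#' @export
read_cell_force_field <- function(path, axis = c(1, 0)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- read.csv(path)
  need <- c("post_id", "x_um", "y_um", "fx_nN", "fy_nN")
  if (!all(need %in% names(d)))
    stop("expected header 'post_id,x_um,y_um,fx_nN,fy_nN' in ", path,
         call. = FALSE)
  cell_force_field(d$x_um, d$y_um, d$fx_nN, d$fy_nN, axis = axis)
}
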