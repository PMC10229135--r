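#' Coordinate trajectory container
#'
#' @param coords Numeric array `frames x atoms x 3` (Angstrom), or a
#'   single `atoms x 3` matrix for a one-frame trajectory.
#' @param atom_labels Unique atom labels; defaults to `A1, A2, ...`.
#' @param frame_times Optional frame times.
#' @return Object of class `md_trajectory`.
#' @export
trajectory <- function(coords, atom_labels = NULL, frame_times = NULL) {
  if (is.matrix(coords)) coords <- array(coords, c(1, dim(coords)))
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3,
            dim(coords)[1] >= 1)
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  n_atoms <- dim(coords)[2]
  if (is.null(atom_labels)) atom_labels <- paste0("A", seq_len(n_atoms))
  if (anyDuplicated(atom_labels)) stop("atom labels must be unique")
  if (length(atom_labels) != n_atoms)
    stop("atom_labels length must match the atom dimension")
  structure(list(coords = coords, atom_labels = atom_labels,
                 frame_times = frame_times),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<md_trajectory> %d frames, %d atoms\n", d[1], d[2]))
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1]
frame_matrix <- function(traj, i) {
  m <- traj$coords[i, , , drop = FALSE]
  matrix(m, dim(traj$coords)[2], 3)
}

resolve_selection <- function(traj, selection) {
  n <- dim(traj$coords)[2]
  if (is.null(selection)) return(seq_len(n))
  if (is.character(selection))
    selection <- match(selection, traj$atom_labels)
  selection <- as.integer(selection)
  if (anyNA(selection) || anyDuplicated(selection) ||
      any(selection < 1) || any(selection > n))
    stop("invalid atom selection")
  selection
}

#' Read a multi-frame XYZ file as a trajectory
#'
#' Plain XYZ dialect: per frame an atom count line, a comment line, then
#' `label x y z` rows.  Coordinates are Angstrom.
#'
#' @param path File path.
#' @return An `md_trajectory`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  i <- 1L
  frames <- list()
  labels <- NULL
  while (i <= length(lines)) {
    n <- as.integer(trimws(lines[i]))
    if (is.na(n)) stop("malformed XYZ: expected atom count at line ", i)
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    lab <- vapply(parts, `[[`, "", 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (is.null(labels)) labels <- lab
    frames[[length(frames) + 1]] <- xyz
    i <- i + 2L + n
  }
  coords <- array(NA_real_, c(length(frames), length(labels), 3))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  if (anyDuplicated(labels))
    labels <- paste0(labels, "_", seq_along(labels))
  trajectory(coords, labels)
}

#' Write a trajectory as multi-frame XYZ
#'
#' @param traj An `md_trajectory`.
#' @param path Output path.
#' @export
write_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- dim(traj$coords)[2]
  for (f in seq_len(n_frames(traj))) {
    writeLines(c(as.character(n), paste("frame", f)), con)
    m <- frame_matrix(traj, f)
    writeLines(sprintf("%s %.6f %.6f %.6f", traj$atom_labels,
                       m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' Read / write the long-format CSV trajectory dialect
#'
#' Columns: `frame`, `atom`, `x`, `y`, `z`.
#'
#' @param path File path.
#' @return An `md_trajectory` (for `read_traj_csv`).
#' @export
read_traj_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "atom", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("trajectory CSV needs columns: ", paste(need, collapse = ", "))
  frames <- sort(unique(df$frame))
  labels <- unique(df$atom[df$frame == frames[1]])
  coords <- array(NA_real_, c(length(frames), length(labels), 3))
  for (fi in seq_along(frames)) {
    sub <- df[df$frame == frames[fi], ]
    ord <- match(labels, sub$atom)
    coords[fi, , ] <- as.matrix(sub[ord, c("x", "y", "z")])
  }
  trajectory(coords, labels)
}

#' @rdname read_traj_csv
#' @param traj An `md_trajectory` (for `write_traj_csv`).
#' @export
write_traj_csv <- function(traj, path) {
  nf <- n_frames(traj)
  na <- dim(traj$coords)[2]
  df <- data.frame(
    frame = rep(seq_len(nf), each = na),
    atom = rep(traj$atom_labels, nf),
    x = as.vector(t(traj$coords[, , 1, drop = TRUE])),
    y = as.vector(t(traj$coords[, , 2, drop = TRUE])),
    z = as.vector(t(traj$coords[, , 3, drop = TRUE])))
  if (nf == 1) {  # drop = TRUE collapses the frame dimension
    df$x <- traj$coords[1, , 1]
    df$y <- traj$coords[1, , 2]
    df$z <- traj$coords[1, , 3]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
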