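# Extended-XYZ and delimited time-series I/O.

#' Write / read extended-XYZ
#'
#' One record per site (cores and shells), with per-particle fields
#' `species`, `pos` (A), `role` (`core`|`shell`), `owner` (file row index
#' of the owning core for shells, 0 for cores), `charge` (e), `mass`
#' (amu), `spring` (eV/A^2, 0 for cores) and `vel` (A/fs). Shell records
#' immediately follow their owner core by convention. The cell is stored in
#' the `Lattice="ax ay az bx by bz cx cy cz"` header convention (row-major
#' lattice vectors); open systems omit it.
#'
#' The file does not carry the bonded topology; use [detect_topology()] (or
#' a topology the caller keeps) after reading.
#'
#' @param sys a `particle_system`.
#' @param path file path.
#' @param comment extra text appended to the header line.
#' @param append append a frame to an existing trajectory file.
#' @return `read_xyz()` returns a `particle_system` (without topology).
#' @export
write_xyz <- function(sys, path, comment = "", append = FALSE) {
  n <- n_atoms(sys); ns <- n_shells(sys)
  owner2shell <- rep(NA_integer_, n)
  if (ns > 0) owner2shell[sys$shells$owner] <- seq_len(ns)
  # interleave: core, then its shell
  rows <- character(n + ns)
  rowno <- 0
  core_row <- integer(n)
  for (i in seq_len(n)) {
    rowno <- rowno + 1
    core_row[i] <- rowno
    rows[rowno] <- ""
  }
  # two passes: first assign row numbers with shells interleaved
  rowno <- 0
  core_row <- integer(n)
  shell_row <- integer(ns)
  for (i in seq_len(n)) {
    rowno <- rowno + 1; core_row[i] <- rowno
    if (!is.na(owner2shell[i])) { rowno <- rowno + 1; shell_row[owner2shell[i]] <- rowno }
  }
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  out <- character(n + ns)
  for (i in seq_len(n)) {
    out[core_row[i]] <- paste(sys$species[i],
      fmt(sys$pos[i, 1]), fmt(sys$pos[i, 2]), fmt(sys$pos[i, 3]),
      "core", 0L, fmt(sys$charge[i]), fmt(sys$mass[i]), fmt(0),
      fmt(sys$vel[i, 1]), fmt(sys$vel[i, 2]), fmt(sys$vel[i, 3]))
  }
  if (ns > 0) for (k in seq_len(ns)) {
    i <- sys$shells$owner[k]
    out[shell_row[k]] <- paste(sys$species[i],
      fmt(sys$shells$pos[k, 1]), fmt(sys$shells$pos[k, 2]), fmt(sys$shells$pos[k, 3]),
      "shell", core_row[i], fmt(sys$shells$charge[k]), fmt(sys$shells$mass[k]),
      fmt(sys$shells$k[k]),
      fmt(sys$shells$vel[k, 1]), fmt(sys$shells$vel[k, 2]), fmt(sys$shells$vel[k, 3]))
  }
  header <- paste0(
    if (!is.null(sys$cell))
      paste0('Lattice="', paste(fmt(t(sys$cell)[]), collapse = " "), '" ') else "",
    'Properties=species:S:1:pos:R:3:role:S:1:owner:I:1:charge:R:1:mass:R:1:spring:R:1:vel:R:3',
    if (nzchar(comment)) paste0(" ", comment) else "")
  lines <- c(as.character(n + ns), header, out)
  if (append) cat(lines, file = path, sep = "\n", append = TRUE)
  else writeLines(lines, path)
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  nsite <- as.integer(lines[1])
  header <- lines[2]
  cell <- NULL
  lat <- regmatches(header, regexec('Lattice="([^"]*)"', header))[[1]]
  if (length(lat) == 2) {
    v <- as.numeric(strsplit(trimws(lat[2]), "\\s+")[[1]])
    cell <- matrix(v, 3, 3, byrow = TRUE)
  }
  body <- lines[3:(2 + nsite)]
  toks <- strsplit(trimws(body), "\\s+")
  species <- vapply(toks, `[`, "", 1)
  num <- function(col) vapply(toks, function(t) as.numeric(t[col]), 0)
  pos <- cbind(num(2), num(3), num(4))
  role <- vapply(toks, `[`, "", 5)
  owner_row <- vapply(toks, function(t) as.integer(t[6]), 0L)
  charge <- num(7); mass <- num(8); spring <- num(9)
  vel <- cbind(num(10), num(11), num(12))
  is_core <- role == "core"
  if (!all(role %in% c("core", "shell"))) stop("unknown role field in ", path)
  core_rows <- which(is_core)
  row2core <- match(seq_len(nsite), core_rows)   # file row -> core index
  shells <- NULL
  if (any(!is_core)) {
    sh_rows <- which(!is_core)
    own <- row2core[owner_row[sh_rows]]
    if (anyNA(own)) stop("shell with missing owner in ", path)
    shells <- list(owner = own, pos = pos[sh_rows, , drop = FALSE],
                   mass = mass[sh_rows], charge = charge[sh_rows],
                   k = spring[sh_rows], vel = vel[sh_rows, , drop = FALSE])
  }
  particle_system(species[core_rows], pos[core_rows, , drop = FALSE],
                  mass[core_rows], charge[core_rows],
                  vel = vel[core_rows, , drop = FALSE],
                  shells = shells, cell = cell)
}

#' Write / read scalar time series
#'
#' Tab-delimited text with unit-annotated column names (e.g. `time_fs`,
#' `e_total_eV`, `T_phys_K`), written at full precision so that derived
#' quantities (drift slopes, statistics) survive a round trip.
#'
#' @param series data.frame.
#' @param path file path.
#' @return `read_timeseries()` returns the data.frame.
#' @export
write_timeseries <- function(series, path) {
  utils::write.table(format(series, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  required <- c("time_fs")
  miss <- setdiff(required, names(df))
  if (length(miss)) stop("time series missing columns: ",
                         paste(miss, collapse = ", "))
  df
}
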