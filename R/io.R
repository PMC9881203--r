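#' Write a QENS spectrum to CSV
#'
#' Long format with columns (q, E, S, dS) and `# key: value` header lines
#' carrying the temperature and units; one file per temperature.
#'
#' @param spectrum a \code{qens_spectrum}.
#' @param path output file.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# temperature_K: %.6g", spectrum$temperature),
               "# units: q=1/Angstrom E=ueV S=arb"), con)
  d <- data.frame(q = rep(spectrum$q_values, each = length(spectrum$energy_grid)),
                  E = rep(spectrum$energy_grid, length(spectrum$q_values)),
                  S = as.vector(t(spectrum$intensities)),
                  dS = as.vector(t(spectrum$uncertainties)))
  utils::write.csv(d, con, row.names = FALSE)
}

#' Read a QENS spectrum from CSV
#' @param path file written by [write_spectrum_csv()] (or matching layout).
#' @return a \code{qens_spectrum}.
#' @export
read_spectrum_csv <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  tline <- grep("temperature_K", hdr, value = TRUE)
  if (length(tline) == 0) stop("spectrum file lacks a temperature header")
  T <- as.numeric(sub(".*temperature_K:\\s*", "", tline[1]))
  d <- utils::read.csv(path, comment.char = "#")
  q <- sort(unique(d$q))
  E <- sort(unique(d$E))
  S <- matrix(NA_real_, length(q), length(E))
  dS <- S
  iq <- match(d$q, q); iE <- match(d$E, E)
  S[cbind(iq, iE)] <- d$S
  dS[cbind(iq, iE)] <- d$dS
  qens_spectrum(T, q, E, S, dS)
}

#' Write a trajectory as extended-XYZ-style text
#'
#' Frame layout: atom count; a comment line `time=<ns> box=<Lx> <Ly> <Lz>`;
#' then one line per atom: species x y z charge mass chain.
#'
#' @param traj a \code{trajectory}.
#' @param path output file.
#' @export
write_trajectory_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n_atoms <- dim(traj$coords)[2]
  sp <- if (is.null(traj$species)) rep("X", max(traj$chain_id))
        else traj$species
  ch <- if (is.null(traj$charge)) rep(0, n_atoms) else traj$charge
  for (t in seq_along(traj$times)) {
    writeLines(as.character(n_atoms), con)
    writeLines(sprintf("time=%.9g box=%.9g %.9g %.9g wrapped=%d",
                       traj$times[t], traj$box[1], traj$box[2], traj$box[3],
                       as.integer(traj$wrapped)), con)
    writeLines(sprintf("%s %.9g %.9g %.9g %.5g %.5g %d",
                       sp[traj$chain_id], traj$coords[t, , 1],
                       traj$coords[t, , 2], traj$coords[t, , 3],
                       ch, traj$mass, traj$chain_id), con)
  }
}

#' Read an extended-XYZ-style trajectory
#' @param path file written by [write_trajectory_xyz()].
#' @return a \code{trajectory}.
#' @export
read_trajectory_xyz <- function(path) {
  lines <- readLines(path)
  i <- 1L
  frames <- list(); times <- c(); box <- NULL; wrapped <- TRUE
  chain_id <- NULL; charge <- NULL; mass <- NULL; species <- NULL
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    hdr <- lines[i + 1L]
    times <- c(times, as.numeric(sub(".*time=([^ ]+).*", "\\1", hdr)))
    bx <- as.numeric(strsplit(sub(".*box=", "", hdr), " ")[[1]][1:3])
    box <- bx
    wrapped <- grepl("wrapped=1", hdr)
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- do.call(rbind, strsplit(trimws(block), "\\s+"))
    frames[[length(frames) + 1L]] <-
      matrix(as.numeric(parts[, 2:4]), ncol = 3)
    if (is.null(chain_id)) {
      chain_id <- as.integer(parts[, 7])
      charge <- as.numeric(parts[, 5])
      mass <- as.numeric(parts[, 6])
      species <- parts[!duplicated(chain_id), 1]
    }
    i <- i + 2L + n
  }
  co <- array(0, c(length(frames), nrow(frames[[1]]), 3))
  for (t in seq_along(frames)) co[t, , ] <- frames[[t]]
  trajectory(times, co, box, chain_id, species = species, charge = charge,
             mass = mass, wrapped = wrapped)
}

#' Write / read a dynamics series as CSV
#' @param series a \code{dynamics_series}.
#' @param path file path.
#' @export
write_series_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("dynamics_series", class(out))
  out
}

#' Write a pressure series as CSV
#' @param series data.frame with time and component columns.
#' @param path file path.
#' @export
write_pressure_csv <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE)
}

#' @rdname write_pressure_csv
#' @export
read_pressure_csv <- function(path) utils::read.csv(path)
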