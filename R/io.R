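# Conformation and result serialization: TSV coordinates, cosmetic CA-only
# PDB, trace CSV and JSON summary.

#' Write a conformation as tab-separated text
#'
#' One line per monomer: 1-based index, residue letter, x, y, z (unscaled
#' lattice units).
#'
#' @param conf An `hp_conformation`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_conformation_tsv <- function(conf, path) {
  conf <- as_conformation(conf)
  df <- data.frame(index = seq_len(nrow(conf$coords)),
                   residue = strsplit(conf$sequence, "")[[1]],
                   x = conf$coords[, 1], y = conf$coords[, 2],
                   z = conf$coords[, 3])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a conformation from tab-separated text
#'
#' @param path File written by [write_conformation_tsv()].
#' @return An `hp_conformation`.
#' @export
read_conformation_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("integer", "character", "integer",
                                         "integer", "integer"))
  conformation(paste(df$residue, collapse = ""),
               as.matrix(df[, c("x", "y", "z")]))
}

#' Write a CA-only PDB file for a lattice conformation
#'
#' Cosmetic export for molecular viewers: each monomer becomes one CA atom
#' (residue ALA for H, GLY for P) with lattice units scaled so one lattice
#' step (length sqrt(2)) is about 3.8 Angstrom, the CA-CA virtual bond.
#' The geometry remains a lattice walk; this is *not* a physical model.
#'
#' @param conf An `hp_conformation`.
#' @param path Output file.
#' @param scale Angstrom per lattice unit (default 3.8 / sqrt(2) ~ 2.69;
#'   a documented, non-physical convenience).
#' @return `path`, invisibly.
#' @export
write_conformation_pdb <- function(conf, path, scale = 3.8 / sqrt(2)) {
  conf <- as_conformation(conf)
  xyz <- conf$coords * scale
  res <- ifelse(conf$is_h, "ALA", "GLY")
  lines <- sprintf(
    "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(xyz)), res, seq_len(nrow(xyz)),
    xyz[, 1], xyz[, 2], xyz[, 3])
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write the artifacts of a folding run
#'
#' Emits the best conformation (TSV, optional PDB), the per-iteration trace
#' (CSV with an `event` column combining move/stall, minimum_stored and
#' retreat/restart markers) and a JSON summary of energies, counters and
#' parameters.
#'
#' @param result An `hp_fold_result`.
#' @param dir Output directory (created if missing).
#' @param pdb Also write the cosmetic CA-only PDB?
#' @return Named character vector of the files written, invisibly.
#' @export
write_fold_result <- function(result, dir, pdb = FALSE) {
  if (!inherits(result, "hp_fold_result")) stop("expected an hp_fold_result")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(coords = file.path(dir, "best_conformation.tsv"),
             trace = file.path(dir, "trace.csv"),
             summary = file.path(dir, "summary.json"))
  write_conformation_tsv(result$best_conformation, files[["coords"]])
  if (!is.null(result$trace)) {
    tr <- result$trace
    ev <- tr$event
    ev[tr$minimum_stored] <- paste0(ev[tr$minimum_stored], ";minimum_stored")
    if (nrow(result$retreat_events)) {
      at <- match(result$retreat_events$iteration, tr$iteration)
      ev[at] <- paste0(ev[at], ";", result$retreat_events$source)
    }
    out <- data.frame(iteration = tr$iteration,
                      current_fitness = tr$current_fitness,
                      current_energy = tr$current_energy,
                      best_energy = tr$best_energy,
                      event = ev)
    utils::write.csv(out, files[["trace"]], row.names = FALSE)
  }
  summary <- list(
    sequence = result$sequence,
    length = nchar(result$sequence),
    best_energy = result$best_energy,
    best_fitness = result$best_fitness,
    iterations = result$iterations,
    retreats = result$retreats,
    restarts = result$restarts,
    discards = result$discards,
    minima_detected = result$minima_detected,
    minima_stored = result$minima_stored,
    memory_size = result$memory_size,
    elite_size = result$elite_size,
    seed = result$params$seed,
    parameters = result$params[c("max_iterations", "max_stable", "proximity",
                                 "memory_rate", "elite_release",
                                 "elite_capacity", "period_h", "period_p",
                                 "allow_end_moves", "literal_fitness",
                                 "max_runner_up")])
  jsonlite::write_json(summary, files[["summary"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  if (pdb) {
    files <- c(files, pdb = file.path(dir, "best_conformation.pdb"))
    write_conformation_pdb(result$best_conformation, files[["pdb"]])
  }
  invisible(files)
}
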