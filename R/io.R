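# Readers and writers: multi-model PDB (hand-rolled fixed-column format,
# no R PDB parser is available), FASTA via Biostrings, tabular peak /
# restraint / titration files with a metadata comment header, and JSON
# dumps for topologies and schedules.

.pkg_version <- function() {
  tryCatch(as.character(utils::packageVersion("dnarmd")),
           error = function(e) "0.0.0")
}

# tiny polynomial hash for config fingerprints (no digest dependency)
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.meta_header <- function(seed = NA, config = NULL) {
  sprintf("# dnarmd %s; seed=%s; config=%s", .pkg_version(),
          ifelse(is.na(seed), "NA", seed), .config_hash(config))
}

#' Read a DNA sequence from a FASTA file
#'
#' @param path FASTA file; the first record is used
#' @return upper-case sequence string
#' @export
read_fasta_sequence <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) stop("no sequences in ", path)
  toupper(as.character(seqs[[1]]))
}

# ---- PDB --------------------------------------------------------------------

.pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                           element) {
  name4 <- if (nchar(name) >= 4) substr(name, 1, 4) else paste0(" ", name)
  sprintf("ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name4, resname, chain, resno, x, y, z, 1, 0, element)
}

#' Write a structure or ensemble as a multi-model PDB file
#'
#' Standard fixed-column PDB with MODEL/ENDMDL records (a single
#' structure is written as one model). Chains: sense strand A, complement
#' B, ligands C, D, ... A REMARK header carries the package version.
#'
#' @param x a `dna_structure` or `dna_ensemble`
#' @param path output file
#' @param seed optional seed recorded in the header
#' @return `path`, invisibly
#' @export
write_pdb_ensemble <- function(x, path, seed = NA) {
  models <- if (inherits(x, "dna_ensemble")) x$models else list(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("REMARK   4 %s", .meta_header(seed, list(n = length(models)))),
             con)
  for (m in seq_along(models)) {
    s <- models[[m]]
    writeLines(sprintf("MODEL     %4d", m), con)
    lines <- vapply(seq_len(nrow(s)), function(i) {
      .pdb_atom_line(i, s$atom[i], s$resname[i], s$chain[i], s$resno[i],
                     s$x[i], s$y[i], s$z[i], s$element[i])
    }, character(1))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB file as an ensemble
#'
#' Parses ATOM/HETATM records (fixed columns); MODEL/ENDMDL blocks become
#' ensemble members, and a file without MODEL records is accepted as a
#' single-model ensemble. Malformed ATOM records raise an error naming the
#' line number.
#'
#' @param path PDB file
#' @param topology optional `duplex_topology` attached to every model
#' @return a `dna_ensemble`
#' @export
read_pdb_ensemble <- function(path, topology = NULL) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty PDB file: ", path)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)
  model_id <- cumsum(rec == "MODEL ")
  if (max(model_id) == 0) model_id <- rep(1L, length(lines))
  models <- list()
  for (mid in sort(unique(model_id[is_atom]))) {
    sel <- which(is_atom & model_id == mid)
    ln <- lines[sel]
    x <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
    y <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
    z <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
    resno <- suppressWarnings(as.integer(substr(ln, 23, 26)))
    bad <- which(is.na(x) | is.na(y) | is.na(z) | is.na(resno))
    if (length(bad)) {
      stop("malformed ATOM record at line ", sel[bad[1]], " of ", path)
    }
    df <- data.frame(
      resno = resno,
      resname = trimws(substr(ln, 18, 20)),
      atom = trimws(substr(ln, 13, 16)),
      element = trimws(substr(ln, 77, 78)),
      chain = substr(ln, 22, 22),
      x = x, y = y, z = z, stringsAsFactors = FALSE)
    no_el <- df$element == ""
    df$element[no_el] <- substr(gsub("[^A-Za-z]", "", df$atom[no_el]), 1, 1)
    models[[length(models) + 1]] <-
      .new_structure(df, topology, model_id = length(models) + 1L)
  }
  .new_ensemble(models,
                info = data.frame(model = seq_along(models),
                                  energy = NA_real_,
                                  restraint_energy = NA_real_,
                                  violations = NA_integer_,
                                  seed = NA_integer_))
}

# ---- peak lists / restraints / titrations ----------------------------------

#' Write / read a NOESY peak list (TSV)
#'
#' Tab-separated with a `#` metadata header carrying the reference peak,
#' cutoff and seed; columns `proton_i`, `proton_j`, `resname_i`,
#' `resname_j`, `volume`, `mixing_time_ms`.
#'
#' @param peaks a `noe_peaks` object
#' @param path file path
#' @return `path` (write) or a `noe_peaks` object (read)
#' @export
write_peaks <- function(peaks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(.meta_header(attr(peaks, "seed"), list(cutoff = attr(peaks, "cutoff"))),
               sprintf("# reference_peak=%s|%s cutoff=%g seed=%d",
                       attr(peaks, "reference_peak")[1],
                       attr(peaks, "reference_peak")[2],
                       attr(peaks, "cutoff"), attr(peaks, "seed"))), con)
  utils::write.table(as.data.frame(peaks), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_peaks
#' @export
read_peaks <- function(path) {
  lines <- readLines(path)
  meta <- grep("^# reference_peak=", lines, value = TRUE)
  df <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                          stringsAsFactors = FALSE)
  out <- structure(df, class = c("noe_peaks", "data.frame"))
  if (length(meta)) {
    ref <- sub("^# reference_peak=([^ ]+) .*$", "\\1", meta[1])
    attr(out, "reference_peak") <- strsplit(ref, "|", fixed = TRUE)[[1]]
    attr(out, "cutoff") <- as.numeric(sub(".* cutoff=([0-9.]+).*", "\\1", meta[1]))
    attr(out, "seed") <- as.integer(sub(".* seed=([0-9]+).*", "\\1", meta[1]))
  }
  out
}

#' Write / read a distance-restraint table (TSV)
#' @param set a `restraint_set`
#' @param path file path
#' @return `path` (write) or a `restraint_set` (read)
#' @export
write_restraints <- function(set, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.meta_header(NA, list(n = nrow(set))), con)
  utils::write.table(as.data.frame(set), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_restraints
#' @export
read_restraints <- function(path) {
  lines <- readLines(path)
  df <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                          stringsAsFactors = FALSE)
  .new_restraint_set(df)
}

#' Export restraints in X-PLOR "assign" syntax
#'
#' Writes `assign (resid i and name a) (resid j and name b) d dminus
#' dplus` lines for interoperability with classic structure-calculation
#' software.
#'
#' @param set a `restraint_set`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_xplor_restraints <- function(set, path) {
  lines <- sprintf(
    "assign (resid %3d and name %-4s) (resid %3d and name %-4s) %6.2f %5.2f %5.2f",
    set$resno_i, set$atom_i, set$resno_j, set$atom_j,
    set$r, set$r - set$lower, set$upper - set$r)
  writeLines(c(paste("!", .meta_header(NA, list(n = nrow(set)))), lines), path)
  invisible(path)
}

#' Write / read an FID titration table (CSV)
#'
#' Columns `drug_total_M`, `replicate`, `fraction`; the duplex
#' concentration and seed are carried in a `#` metadata header.
#'
#' @param table a `titration_table`
#' @param path file path
#' @return `path` (write) or a `titration_table` (read)
#' @export
write_titration <- function(table, path) {
  spec <- attr(table, "spec")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(.meta_header(spec$seed, spec),
               sprintf("# duplex_total_M=%g seed=%d", spec$duplex_total,
                       spec$seed)), con)
  utils::write.table(as.data.frame(table), con, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_titration
#' @export
read_titration <- function(path) {
  lines <- readLines(path)
  meta <- grep("^# duplex_total_M=", lines, value = TRUE)
  df <- utils::read.csv(text = lines[!startsWith(lines, "#")],
                        stringsAsFactors = FALSE)
  out <- structure(df, class = c("titration_table", "data.frame"))
  if (length(meta)) {
    dt <- as.numeric(sub("^# duplex_total_M=([0-9.eE+-]+).*", "\\1", meta[1]))
    attr(out, "spec") <- list(duplex_total = dt)
  }
  out
}

# ---- JSON dumps -------------------------------------------------------------

#' Dump a duplex topology as JSON
#' @param topology a `duplex_topology`
#' @param path optional output file; if NULL the JSON string is returned
#' @return JSON string or `path`
#' @export
topology_json <- function(topology, path = NULL) {
  j <- jsonlite::toJSON(list(sense = topology$sense,
                             complement = topology$complement,
                             n = topology$n, pairs = topology$pairs),
                        auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(j)
  writeLines(j, path)
  invisible(path)
}

#' Serialize / restore an annealing schedule (JSON)
#' @param schedule an `annealing_schedule`
#' @param path file path
#' @return `path` (write) or an `annealing_schedule` (read)
#' @export
write_schedule <- function(schedule, path) {
  jsonlite::write_json(list(stages = schedule$stages, n_min = schedule$n_min,
                            scale = schedule$scale),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  j$stages$nsteps <- as.integer(j$stages$nsteps)
  j$stages$average <- as.integer(j$stages$average)
  structure(list(stages = j$stages, n_min = as.integer(j$n_min),
                 scale = j$scale),
            class = "annealing_schedule")
}
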