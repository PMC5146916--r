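# Plain-text structure and result output: XYZ for visualization, a topology
# table and ensemble TSVs for reproducibility.

#' Write an XYZ structure or trajectory frame
#'
#' One record per bead: element-like label (P/S/B/C) and x, y, z in LJ
#' units. For a `poremd_system` the labels come from the bead table; a bare
#' position matrix needs `labels`.
#'
#' @param x A `poremd_system` or an N x 3 position matrix.
#' @param file Output path (opened in append mode when `append = TRUE`, so
#'   successive calls build a multi-frame trajectory).
#' @param labels Bead labels when `x` is a matrix.
#' @param comment Comment line (step index and LJ time, typically).
#' @param append Append a frame instead of overwriting.
#' @return `file`, invisibly.
#' @export
write_xyz <- function(x, file, labels = NULL, comment = "", append = FALSE) {
  if (inherits(x, "poremd_system")) {
    labels <- x$beads$label
    pos <- x$pos
    if (comment == "") comment <- sprintf("step %d time %.6g", x$step, x$time)
  } else {
    pos <- as.matrix(x)
    if (is.null(labels)) labels <- rep("X", nrow(pos))
  }
  con <- file(file, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(c(as.character(nrow(pos)), comment), con)
  writeLines(sprintf("%s %.8f %.8f %.8f", labels, pos[, 1], pos[, 2], pos[, 3]),
             con)
  invisible(file)
}

#' Write the plain-text topology table
#'
#' One TSV row per bead: index, kind label, group, bonded partners
#' (comma-separated) and tether anchor (for membrane beads).
#'
#' @param system A `poremd_system`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_topology_table <- function(system, file) {
  stopifnot(inherits(system, "poremd_system"))
  n <- nrow(system$beads)
  partners <- rep("", n)
  for (b in seq_len(nrow(system$bonds))) {
    i <- system$bonds$i[b]; j <- system$bonds$j[b]
    partners[i] <- paste(c(partners[i][partners[i] != ""], j), collapse = ",")
    partners[j] <- paste(c(partners[j][partners[j] != ""], i), collapse = ",")
  }
  teth <- ifelse(system$tether_k > 0 | system$frozen &
                   system$beads$group == "membrane",
                 sprintf("%.6f,%.6f,%.6f", system$anchor[, 1],
                         system$anchor[, 2], system$anchor[, 3]), "")
  tab <- data.frame(
    bead = seq_len(n), kind = system$beads$label,
    group = system$beads$group, bonded = partners,
    tether_k = ifelse(system$beads$group == "membrane",
                      ifelse(system$mode == "immobile", "Inf",
                             format(system$tether_k)), ""),
    anchor = teth)
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write and read ensemble result tables
#'
#' One TSV row per trajectory: seed, status, translocation time in steps and
#' LJ units.
#'
#' @param ensemble A `poremd_ensemble`.
#' @param file Path to the TSV.
#' @return `write_ensemble_tsv()` returns `file` invisibly;
#'   `read_ensemble_tsv()` returns a tibble.
#' @export
write_ensemble_tsv <- function(ensemble, file) {
  stopifnot(is.data.frame(ensemble))
  cols <- intersect(c("traj", "seed", "status", "tau_steps", "tau"),
                    names(ensemble))
  utils::write.table(as.data.frame(ensemble)[, cols], file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_ensemble_tsv
#' @export
read_ensemble_tsv <- function(file) {
  tibble::as_tibble(utils::read.table(file, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
}
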