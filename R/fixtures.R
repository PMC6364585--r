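#' Generate a labelled aggregate fixture without running dynamics
#'
#' Builds a geometrically plausible packed-sphere aggregate (cell centres,
#' types, contact graph and per-cell free surface areas) for exercising the
#' sorting analysis. `"shuffled"` assigns types at random; `"sorted"` places
#' type 1 on the innermost cells; `"shell"` additionally gives the enclosed
#' type-1 core zero free surface (an idealised fully inside-out sorted
#' state). Free areas are a geometric proxy: each contact occludes 1/12 of a
#' cell's surface (the close-packing coordination number).
#'
#' @param n_cells Number of cells (>= 2).
#' @param type_ratio Fraction of type-1 cells.
#' @param arrangement `"shuffled"`, `"sorted"` or `"shell"`.
#' @param spacing Centre-to-centre spacing of touching cells (length unit).
#' @return An object of class `sce_fixture`: list with `cells` (tibble
#'   compatible with [cell_frame()]) and `contacts`.
#' @examples
#' set.seed(1)
#' fx <- generate_labelled_aggregate(30, arrangement = "sorted")
#' sorting_indices(fx$cells, fx$contacts, n_shuffles = 200)
#' @export
generate_labelled_aggregate <- function(n_cells, type_ratio = 0.5,
                                        arrangement = c("shuffled", "sorted", "shell"),
                                        spacing = 1) {
  arrangement <- match.arg(arrangement)
  stopifnot(n_cells >= 2, type_ratio >= 0, type_ratio <= 1)
  n1 <- round(type_ratio * n_cells)
  if (arrangement != "shuffled" && (n1 == 0 || n1 == n_cells))
    stop("sorted/shell arrangements need both types present")
  ctr <- packed_centres(n_cells, spacing)
  ctr <- sweep(ctr, 2, colMeans(ctr))
  r <- sqrt(rowSums(ctr^2))
  d <- as.matrix(stats::dist(ctr))
  pairs <- which(upper.tri(d) & d <= 1.35 * spacing, arr.ind = TRUE)
  contacts <- tibble::tibble(cell_a = as.integer(pairs[, 1]),
                             cell_b = as.integer(pairs[, 2]))
  n_contacts <- tabulate(c(contacts$cell_a, contacts$cell_b), nbins = n_cells)
  area <- 4 * pi * (spacing / 2)^2
  free_area <- area * pmax(0, 1 - n_contacts / 12)
  types <- rep(2L, n_cells)
  if (arrangement == "shuffled") {
    types[sample(n_cells, n1)] <- 1L
  } else {
    types[order(r)[seq_len(n1)]] <- 1L
    if (arrangement == "shell") free_area[types == 1L] <- 0
  }
  cells <- tibble::tibble(cell = seq_len(n_cells), type = types,
                          x = ctr[, 1], y = ctr[, 2], z = ctr[, 3],
                          n_contacts = n_contacts,
                          area = area, free_area = free_area)
  structure(list(cells = cells, contacts = contacts,
                 arrangement = arrangement),
            class = "sce_fixture")
}

#' @export
print.sce_fixture <- function(x, ...) {
  cat("<sce_fixture> ", nrow(x$cells), " cells (", x$arrangement, "), ",
      nrow(x$contacts), " contacts\n", sep = "")
  invisible(x)
}
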