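#' Classify the morphology of a field state
#'
#' Labels a (typically final) state as `one_phase` (no dense condensate),
#' `homogeneous` (dense condensate without an enclosed dilute cavity) or
#' `hollow` (a dense component fully enclosing a dilute cavity). The
#' dense mask is `eta > eta_dense`; cavities are dilute regions that a
#' flood fill started from the domain boundary cannot reach.
#'
#' @param state A `field_state` (or a bare `eta` matrix).
#' @param eta_dense Dense-phase threshold (default 0.5, the half-well
#'   point).
#' @param a_min Minimum dense-component area, in cells, for the state to
#'   count as phase-separated.
#' @param hole_min Minimum cavity area, in cells.
#' @return A character scalar: `"one_phase"`, `"homogeneous"` or
#'   `"hollow"`.
#' @examples
#' g <- grid_spec(64, 64)
#' st <- field_fixtures("annulus", g, r_in = 10, r_out = 20)
#' classify_field_state(st)
#' @export
classify_field_state <- function(state, eta_dense = 0.5, a_min = 100,
                                 hole_min = 20) {
  eta <- if (inherits(state, "field_state")) state$eta else state
  if (!all(is.finite(eta))) stop("eta contains non-finite values")
  dense <- eta > eta_dense

  dense_lab <- EBImage::bwlabel(dense)
  dense_sizes <- if (max(dense_lab) > 0) tabulate(dense_lab[dense_lab > 0]) else integer(0)
  if (!length(dense_sizes) || max(dense_sizes) < a_min) return("one_phase")

  ## Flood fill the dilute phase from the domain boundary: dilute
  ## components that never touch the boundary are enclosed cavities.
  dilute_lab <- EBImage::bwlabel(!dense)
  border_labels <- unique(c(dilute_lab[1, ], dilute_lab[nrow(dilute_lab), ],
                            dilute_lab[, 1], dilute_lab[, ncol(dilute_lab)]))
  border_labels <- setdiff(border_labels, 0)
  nlab <- max(dilute_lab)
  if (nlab > 0) {
    sizes <- tabulate(dilute_lab[dilute_lab > 0], nbins = nlab)
    for (lab in setdiff(seq_len(nlab), border_labels)) {
      if (sizes[lab] < hole_min) next
      ## dense components adjacent to this cavity must be large enough
      cav <- dilute_lab == lab
      nb <- shift_mat(cav, 1, 0) | shift_mat(cav, -1, 0) |
        shift_mat(cav, 0, 1) | shift_mat(cav, 0, -1)
      adj <- unique(dense_lab[nb & dense])
      adj <- setdiff(adj, 0)
      if (length(adj) && max(dense_sizes[adj]) >= a_min) return("hollow")
    }
  }
  "homogeneous"
}

#' Sweep initial compositions into a state diagram
#'
#' Runs one simulation per (`zeta_dna`, `zeta_protein`) cell, classifies
#' the final snapshot and assembles the model's state diagram. Each cell
#' gets its own seed (recorded in the output) so the sweep is
#' reproducible cell by cell; cells whose run diverges are recorded as
#' failed rather than aborting the sweep.
#'
#' @param zeta_dna_axis,zeta_protein_axis Numeric axes of initial levels.
#' @param grid A `grid_spec`.
#' @param params Base `model_params` shared by all cells.
#' @param ic Template `initial_condition`; each cell overrides
#'   `zeta_dna`, `zeta_protein` and the seed.
#' @param t_end,save_every Passed to [run_simulation()].
#' @param steady_stop,steady_tol Early-stopping criterion per cell.
#' @param base_seed Seed offset; cell `(i, j)` uses
#'   `base_seed + (j - 1) * length(zeta_dna_axis) + i`.
#' @param resume Optional previous `state_diagram`; only its failed cells
#'   are re-run.
#' @param verbose Print one line per classified cell.
#' @return A `state_diagram`: list with `labels` (matrix, DNA rows by
#'   protein columns), `cells` (one data-frame row per cell: composition,
#'   label, seed, final energy) and the axes.
#' @export
sweep_diagram <- function(zeta_dna_axis, zeta_protein_axis, grid, params,
                          ic = initial_condition(), t_end = 500,
                          save_every = 25, steady_stop = TRUE,
                          steady_tol = 1e-5, base_seed = 100L,
                          resume = NULL, verbose = FALSE) {
  if (!length(zeta_dna_axis) || !length(zeta_protein_axis))
    stop("axes must be non-empty")
  nd <- length(zeta_dna_axis); np <- length(zeta_protein_axis)
  labels <- matrix(NA_character_, nd, np,
                   dimnames = list(zeta_dna = zeta_dna_axis,
                                   zeta_protein = zeta_protein_axis))
  cells <- data.frame(zeta_dna = rep(zeta_dna_axis, np),
                      zeta_protein = rep(zeta_protein_axis, each = nd),
                      label = NA_character_, seed = NA_integer_,
                      energy_final = NA_real_, failed = FALSE)
  if (!is.null(resume)) {
    labels <- resume$labels
    cells <- resume$cells
  }
  for (j in seq_len(np)) for (i in seq_len(nd)) {
    row <- (j - 1) * nd + i
    if (!is.null(resume) && !isTRUE(cells$failed[row]) &&
        !is.na(cells$label[row])) next
    seed_ij <- as.integer(base_seed + row)
    ic_ij <- ic
    ic_ij$zeta_dna <- rep(zeta_dna_axis[i], length(params$k_bind))
    ic_ij$zeta_protein <- zeta_protein_axis[j]
    ic_ij$seed <- seed_ij
    res <- tryCatch({
      tr <- run_simulation(grid, ic_ij, params, t_end = t_end,
                           save_every = save_every,
                           steady_stop = steady_stop,
                           steady_tol = steady_tol)
      list(label = classify_field_state(final_state(tr)),
           energy = tr$energy[length(tr$energy)], failed = FALSE)
    }, error = function(e) list(label = NA_character_, energy = NA_real_,
                                failed = TRUE, msg = conditionMessage(e)))
    labels[i, j] <- res$label
    cells$label[row] <- res$label
    cells$seed[row] <- seed_ij
    cells$energy_final[row] <- res$energy
    cells$failed[row] <- res$failed
    if (verbose)
      message(sprintf("cell (dna = %g, protein = %g): %s",
                      zeta_dna_axis[i], zeta_protein_axis[j],
                      if (res$failed) "FAILED" else res$label))
  }
  sd <- list(labels = labels, cells = cells,
             zeta_dna_axis = zeta_dna_axis,
             zeta_protein_axis = zeta_protein_axis,
             params = params, base_seed = base_seed)
  class(sd) <- "state_diagram"
  sd
}

#' @export
print.state_diagram <- function(x, ...) {
  cat(sprintf("<state_diagram> %d x %d cells\n",
              length(x$zeta_dna_axis), length(x$zeta_protein_axis)))
  print(x$labels)
  invisible(x)
}

#' Plot a state diagram
#'
#' Renders the three-symbol diagram: blue cross (one phase), orange dot
#' (homogeneous condensate), green circle (hollow co-condensate).
#'
#' @param x A `state_diagram`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.state_diagram <- function(x, ...) {
  df <- x$cells
  sym <- c(one_phase = 4, homogeneous = 16, hollow = 1)
  col <- c(one_phase = "blue", homogeneous = "darkorange", hollow = "forestgreen")
  graphics::plot(df$zeta_protein, df$zeta_dna, pch = sym[df$label],
                 col = col[df$label], lwd = 2, cex = 1.6,
                 xlab = expression(zeta[protein]),
                 ylab = expression(zeta[DNA]), ...)
  graphics::legend("topright",
                   legend = c("one phase", "homogeneous", "hollow"),
                   pch = sym, col = col, pt.lwd = 2, bty = "n")
  invisible(x)
}
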