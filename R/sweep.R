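# Parameter sweeps over monitoring and punishment efficiencies: for each
# (m, p) cell, determine feasibility, sample socially optimal networks,
# score their hierarchy, and summarize.

#' Sweep monitoring and punishment efficiencies
#'
#' For every combination of `m_grid` and `p_grid` (holding `N`, `b`, `c_t`,
#' `c_p` fixed at the values in `params_base`), computes the degree
#' constraints, decides feasibility (universal contribution must be more
#' socially efficient than universal free-riding at the optimal link count
#' `K = N * min_in`, and the span of control must cover the required
#' in-degree), and — for feasible cells — draws `n_samples` socially optimal
#' networks, scores each on the Krackhardt measures, and records the graph
#' efficiency (constant across samples of a cell) plus the min/median/max of
#' the hierarchy and composite scores. In infeasible cells universal
#' free-riding is the socially optimal Nash equilibrium and no scores are
#' reported. The sample whose hierarchy score sits at the median is kept as
#' the cell's representative network.
#'
#' @param params_base A [game_params] object; its `m` and `p` are ignored in
#'   favour of the grid values.
#' @param m_grid,p_grid Numeric vectors of monitoring / punishment
#'   efficiencies.
#' @param n_samples Networks to draw per feasible cell.
#' @param seed Integer seed; the whole sweep is deterministic given the seed
#'   (each cell derives its own sub-seed).
#' @return A `coopnet_sweep` tibble with one row per cell: `m`, `p`,
#'   `min_in`, `max_out`, `out_cap` (the cap actually used, clamped to
#'   `N - 1`), `feasible`, `degenerate`, `n_samples`, `E`, `H_min`,
#'   `H_median`, `H_max`, `composite_median`, and a `representative`
#'   list-column of igraph networks (`NULL` where infeasible). Use
#'   [write_sweep()] to persist it and [ggplot2::autoplot()] for a heat map.
#' @examples
#' pars <- game_params(N = 6, b = 2, m = 1, p = 1, c_t = 1, c_p = 0.2)
#' sw <- run_sweep(pars, m_grid = c(2.5, 20), p_grid = c(0.6, 4.6),
#'                 n_samples = 50, seed = 1)
#' dplyr::select(sw, m, p, min_in, max_out, feasible, composite_median)
#' @export
run_sweep <- function(params_base, m_grid, p_grid, n_samples = 1000,
                      seed = NULL) {
  stopifnot(
    inherits(params_base, "game_params"),
    length(m_grid) >= 1, length(p_grid) >= 1, n_samples >= 1
  )
  grid <- tidyr::expand_grid(m = m_grid, p = p_grid)
  cells <- purrr::pmap(
    list(grid$m, grid$p, seq_len(nrow(grid))),
    function(m, p, idx) {
      pars <- game_params(
        N = params_base$N, b = params_base$b, m = m, p = p,
        c_t = params_base$c_t, c_p = params_base$c_p
      )
      dc <- degree_constraints(pars)
      out_cap <- min(dc$max_out, pars$N - 1L)
      base <- tibble::tibble(
        m = m, p = p,
        min_in = dc$min_in, max_out = dc$max_out, out_cap = out_cap,
        feasible = dc$feasible, degenerate = FALSE,
        n_samples = 0L,
        E = NA_real_, H_min = NA_real_, H_median = NA_real_,
        H_max = NA_real_, composite_median = NA_real_,
        representative = list(NULL)
      )
      if (!dc$feasible) {
        return(base)
      }
      spec <- optimal_network_spec(pars$N, dc$min_in, out_cap)
      cell_seed <- if (is.null(seed)) NULL else (seed + idx * 10007L) %% 2147483647L
      nets <- tryCatch(
        sample_optimal(spec, n_samples, seed = cell_seed),
        error = function(e) {
          warning("Cell (m = ", m, ", p = ", p, ") degenerate: ",
            conditionMessage(e),
            call. = FALSE
          )
          NULL
        }
      )
      if (is.null(nets)) {
        base$degenerate <- TRUE
        return(base)
      }
      scores <- purrr::map_dfr(nets, krackhardt_scores)
      ord <- order(scores$hierarchy)
      median_idx <- ord[ceiling(length(ord) / 2)]
      base$n_samples <- length(nets)
      base$E <- scores$efficiency[1]
      base$H_min <- min(scores$hierarchy)
      base$H_median <- stats::median(scores$hierarchy)
      base$H_max <- max(scores$hierarchy)
      base$composite_median <- stats::median(scores$composite)
      base$representative <- list(nets[[median_idx]])
      base
    }
  )
  structure(
    dplyr::bind_rows(cells),
    class = c("coopnet_sweep", class(tibble::tibble()))
  )
}

#' Persist a sweep to disk
#'
#' Writes `sweep.csv` (one row per cell, without the network list-column)
#' and, for each feasible cell, the representative network as
#' `cells/m<m>_p<p>.graphml` under `dir`.
#'
#' @param sweep A `coopnet_sweep` tibble from [run_sweep()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sweep <- function(sweep, dir) {
  stopifnot(inherits(sweep, "coopnet_sweep"))
  dir.create(file.path(dir, "cells"), recursive = TRUE, showWarnings = FALSE)
  flat <- dplyr::select(as.data.frame(sweep), -"representative")
  utils::write.csv(flat, file.path(dir, "sweep.csv"), row.names = FALSE)
  feas <- which(sweep$feasible & !sweep$degenerate)
  for (i in feas) {
    write_network(
      sweep$representative[[i]],
      file.path(dir, "cells", sprintf("m%g_p%g.graphml", sweep$m[i], sweep$p[i]))
    )
  }
  invisible(dir)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heat map of composite hierarchy scores over a sweep
#'
#' Tiles the (m, p) grid coloured by the median composite hierarchy score;
#' infeasible cells (universal free-riding is the socially optimal Nash
#' equilibrium) are shown in grey.
#'
#' @param object A `coopnet_sweep` tibble from [run_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coopnet_sweep
#' @export
autoplot.coopnet_sweep <- function(object, ...) {
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    m = factor(.data$m), p = factor(.data$p)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$m, y = .data$p)) +
    ggplot2::geom_tile(
      ggplot2::aes(fill = .data$composite_median),
      colour = "white"
    ) +
    ggplot2::scale_fill_viridis_c(
      name = "median E × H",
      limits = c(0, 1), na.value = "grey85"
    ) +
    ggplot2::labs(
      x = "monitoring efficiency (m)",
      y = "punishment efficiency (p)",
      title = "Hierarchy of socially optimal monitoring networks"
    ) +
    ggplot2::theme_minimal()
}
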