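## Figure conventions: edges at probability >= 0.5, edge width affine in the
## probability over [cutoff, 1], blue = positive / red = negative partial
## correlation, heatmaps on a shared symmetric color scale centered at zero.

utils::globalVariables(c("x", "y", "value", "panel"))

#' Named node subsets for the standard sub-network views
#'
#' The five thematic views of the full network: age and cognition, sex and
#' cognition, biomarkers and cognition, demographics and biomarkers, and
#' volume versus glucose uptake.
#'
#' @param names Variable names (defaults to the merged dictionary).
#' @return Named list of character vectors.
#' @export
network_subsets <- function(names = dictionary_names(adni_dictionary("merged"))) {
  vol <- grep("^vol_", names, value = TRUE)
  glu <- grep("^glu_", names, value = TRUE)
  bio <- c("amyloid_stage", "apoe4", vol, glu)
  cog <- c("adni_mem", "adni_ef")
  list(age_cognition = c("age", cog, "amyloid_stage", vol),
       sex_cognition = c("sex", "education", cog, "amyloid_stage", vol),
       biomarkers_cognition = c(bio, cog),
       demographics_biomarkers = c("age", "sex", bio),
       volume_glucose = c(vol, glu))
}

#' Restrict a thresholded network to a node subset
#' @param network A [threshold_network()] result.
#' @param nodes Character vector of variable names to keep.
#' @return A `"gcgm_network"` over the subset.
#' @export
subset_network <- function(network, nodes) {
  keep <- network$name_i %in% nodes & network$name_j %in% nodes
  out <- network[keep, , drop = FALSE]
  attr(out, "cutoff") <- attr(network, "cutoff")
  attr(out, "p") <- attr(network, "p")
  attr(out, "nodes") <- intersect(attr(network, "nodes"), nodes)
  class(out) <- c("gcgm_network", "data.frame")
  out
}

.edge_widths <- function(prob, cutoff, wmin = 0.5, wmax = 6) {
  wmin + (wmax - wmin) * (prob - cutoff) / (1 - cutoff)
}

#' Deterministic node layout for a network figure
#' @param network A `"gcgm_network"`.
#' @param layout_seed Seed for the force-directed layout.
#' @return Matrix of node coordinates (rows follow `attr(network, "nodes")`).
#' @export
network_layout <- function(network, layout_seed = 1) {
  nodes <- attr(network, "nodes")
  g <- igraph::graph_from_data_frame(
    network[, c("name_i", "name_j")], directed = FALSE,
    vertices = data.frame(name = nodes))
  set.seed(layout_seed)
  igraph::layout_with_fr(g)
}

#' Render a thresholded network figure
#'
#' Node-link diagram with edge width affine in the inclusion probability over
#' `[cutoff, 1]`, blue edges for positive and red for negative mean partial
#' correlations, and a deterministic layout given `layout_seed`. An empty
#' network renders isolated nodes.
#'
#' @param network A [threshold_network()] result (possibly
#'   [subset_network()]ed).
#' @param file Output file (`.pdf` or `.svg`); `NULL` draws on the current
#'   device.
#' @param layout_seed Layout seed.
#' @param title Optional title.
#' @return The layout coordinates, invisibly.
#' @export
render_network <- function(network, file = NULL, layout_seed = 1,
                           title = NULL) {
  nodes <- attr(network, "nodes")
  cutoff <- attr(network, "cutoff")
  g <- igraph::graph_from_data_frame(
    network[, c("name_i", "name_j")], directed = FALSE,
    vertices = data.frame(name = nodes))
  lay <- network_layout(network, layout_seed)
  if (!is.null(file)) .open_device(file)
  op <- graphics::par(mar = c(0.5, 0.5, if (is.null(title)) 0.5 else 2, 0.5))
  igraph::plot.igraph(
    g, layout = lay,
    edge.width = .edge_widths(network$prob, cutoff),
    edge.color = ifelse(network$mean_partial >= 0, "#2166AC", "#B2182B"),
    vertex.size = 16, vertex.color = "grey92", vertex.frame.color = "grey40",
    vertex.label.color = "black", vertex.label.cex = 0.7,
    main = title)
  graphics::par(op)
  if (!is.null(file)) grDevices::dev.off()
  invisible(lay)
}

.open_device <- function(file, width = 8, height = 8) {
  if (grepl("\\.svg$", file)) grDevices::svg(file, width = width, height = height)
  else if (grepl("\\.png$", file)) grDevices::png(file, width = 150 * width,
                                                  height = 150 * height)
  else grDevices::pdf(file, width = width, height = height)
}

#' Side-by-side Pearson and partial-correlation heatmaps
#'
#' Two heatmaps on a shared symmetric color scale centered at zero (blue
#' positive, red negative), variables in dictionary order.
#'
#' @param pearson Zeroed Pearson matrix (from [pearson_matrix()]).
#' @param partial Zeroed partial-correlation matrix.
#' @param file Output file; `NULL` returns the plot object only.
#' @return The ggplot object, invisibly.
#' @export
render_heatmaps <- function(pearson, partial, file = NULL) {
  nm <- colnames(pearson)
  melt <- function(M, label) {
    data.frame(x = factor(rep(nm, each = length(nm)), levels = nm),
               y = factor(rep(nm, length(nm)), levels = rev(nm)),
               value = as.vector(t(M)), panel = label)
  }
  df <- rbind(melt(pearson, "Pearson correlation"),
              melt(partial, "Partial correlation"))
  lim <- max(abs(df$value[df$x != df$y]), 1e-6)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, fill = value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#B2182B", mid = "white",
                                  high = "#2166AC", midpoint = 0,
                                  limits = c(-lim, lim), name = "r") +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1, vjust = 0.5))
  if (!is.null(file)) ggplot2::ggsave(file, gg, width = 10, height = 5)
  invisible(gg)
}

#' Posterior density of one partial correlation, with its spike at zero
#'
#' Kernel density of the nonzero draws plus a vertical spike bar at zero
#' whose height encodes the posterior probability that the partial
#' correlation is exactly zero (conditional independence). The annotation
#' prints the model-averaged mean, SD and spike mass.
#'
#' @param posterior An [summarize_partials()] result.
#' @param i,j Variable indices or names.
#' @param file Output file; `NULL` draws on the current device.
#' @return List with `mean`, `sd`, `spike_mass`, invisibly.
#' @export
render_density <- function(posterior, i, j, file = NULL) {
  if (is.character(i)) i <- match(i, posterior$names)
  if (is.character(j)) j <- match(j, posterior$names)
  r <- .pair_row(posterior, i, j)
  if (length(r) != 1 || ncol(posterior$samples) == 0)
    stop("no stored draws for this pair")
  draws <- posterior$samples[r, ]
  present <- posterior$adj_samples[r, ] == 1
  w <- posterior$weights / sum(posterior$weights)
  spike <- sum(w[!present])
  m <- posterior$mean_partial[i, j]
  s <- posterior$sd_partial[i, j]
  lab <- sprintf("mean %.3f, sd %.3f, spike %.2f", m, s, spike)
  ttl <- paste(posterior$names[i], "~", posterior$names[j])
  if (!is.null(file)) .open_device(file, width = 6, height = 4)
  if (any(present)) {
    d <- density(draws[present], weights = w[present] / sum(w[present]))
    d$y <- d$y * (1 - spike)
    ymax <- max(d$y, spike)
    plot(d, xlim = range(c(d$x, 0)), ylim = c(0, ymax * 1.05),
         main = ttl, xlab = "partial correlation", ylab = "density")
  } else {
    plot(0, 0, type = "n", xlim = c(-1, 1), ylim = c(0, 1.05), main = ttl,
         xlab = "partial correlation", ylab = "density")
    ymax <- 1
  }
  if (spike > 0)
    graphics::segments(0, 0, 0, spike * ymax, lwd = 6, col = "grey30")
  graphics::mtext(lab, side = 3, line = 0, cex = 0.8)
  if (!is.null(file)) grDevices::dev.off()
  invisible(list(mean = m, sd = s, spike_mass = spike))
}
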