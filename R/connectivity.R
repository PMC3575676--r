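#' Build the initial connection matrix
#'
#' Entry `C[i, j]` is the weight of the synapse from presynaptic neuron `j`
#' onto postsynaptic neuron `i`.  Nine connection groups are laid out from
#' the three populations (granule cells GC, mossy cells MC, interneurons IN):
#' GC->GC starts empty (mossy-fiber sprouting later grows it), each MC and
#' each IN receives afferents from `gc_afferents` distinct granule cells, and
#' all MC- and IN-origin groups are fully connected.  "All" includes the cell
#' itself within the MC->MC and IN->IN groups: at the 1:10,000 reduction each
#' model cell pools thousands of real neurons, so its self-connection stands
#' for the recurrence within that population (and the published weight scales
#' place the resting network in its stability band only with these links
#' present).  Realized weights are drawn from Normal(1.0, 0.2); the rare
#' negative draw is resampled so the matrix is nonnegative from the start.
#'
#' Draw order (for seed reproducibility): the afferent set of each mossy cell
#' in index order, then of each interneuron; then all weights in column-major
#' order of the matrix.
#'
#' @param config a [dg_config()].
#' @return An `n_total` x `n_total` numeric matrix.
#' @examples
#' set.seed(1)
#' C <- build_initial_connectivity(dg_config())
#' mean(C[group_block(dg_config(), "IV")$rows, group_block(dg_config(), "IV")$cols])
#' @export
build_initial_connectivity <- function(config) {
  validate_dg_config(config)
  n <- config$n_total
  gc <- gc_idx(config); mc <- mc_idx(config); inn <- in_idx(config)

  mask <- matrix(FALSE, n, n)
  for (i in c(mc, inn)) {                # groups II and III: sampled GC afferents
    aff <- sample(gc, config$gc_afferents)
    mask[i, aff] <- TRUE
  }
  mask[, mc] <- TRUE                     # groups IV-VI: mossy cells project everywhere
  mask[, inn] <- TRUE                    # groups VII-IX: interneurons project everywhere

  C <- matrix(0, n, n)
  k <- sum(mask)
  w <- stats::rnorm(k, mean = 1.0, sd = 0.2)
  while (any(neg <- w < 0)) {
    w[neg] <- stats::rnorm(sum(neg), mean = 1.0, sd = 0.2)
  }
  C[mask] <- w

  if (config$normalize_inputs) {
    for (cols in list(gc, mc, inn)) {
      blk <- C[, cols, drop = FALSE]
      deg <- rowSums(blk > 0)
      tot <- rowSums(blk)
      fac <- ifelse(tot > 0, deg / tot, 1)
      C[, cols] <- blk * fac
    }
  }
  C
}

#' Connection-group index blocks
#'
#' The nine groups partition the matrix by (presynaptic, postsynaptic)
#' population: I GC->GC, II GC->MC, III GC->IN, IV MC->GC, V MC->MC,
#' VI MC->IN, VII IN->GC, VIII IN->MC, IX IN->IN.
#'
#' @param config a [dg_config()].
#' @param group a roman-numeral label `"I"` ... `"IX"`.
#' @return A list with `rows` (postsynaptic indices) and `cols` (presynaptic
#'   indices) of the block.
#' @export
group_block <- function(config, group) {
  pops <- list(GC = gc_idx(config), MC = mc_idx(config), IN = in_idx(config))
  map <- list(I   = c("GC", "GC"), II  = c("GC", "MC"), III = c("GC", "IN"),
              IV  = c("MC", "GC"), V   = c("MC", "MC"), VI  = c("MC", "IN"),
              VII = c("IN", "GC"), VIII = c("IN", "MC"), IX  = c("IN", "IN"))
  if (!group %in% names(map)) {
    stop(sprintf("unknown connection group '%s'; valid: %s",
                 group, paste(names(map), collapse = ", ")), call. = FALSE)
  }
  pre_post <- map[[group]]
  list(rows = pops[[pre_post[2]]], cols = pops[[pre_post[1]]])
}

#' Mean connectivity of one group
#'
#' Averages `C[i, j]` over every position of the group's index block,
#' including positions holding structural zeros, so that sprouting in an
#' initially empty group (such as GC->GC) registers as growth from zero.
#'
#' @param C connection matrix.
#' @param config a [dg_config()].
#' @param group roman-numeral group label.
#' @return The mean weight of the block.
#' @export
group_mean_connectivity <- function(C, config, group) {
  b <- group_block(config, group)
  mean(C[b$rows, b$cols])
}

group_labels <- function() c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX")
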