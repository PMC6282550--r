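#' Configuration for the forward Gillespie birth-death simulator
#'
#' The simulator is the package's Monte Carlo cross-check: exact-time
#' Gillespie realizations of the same process all analytic laws describe.
#' Conditioning is by rejection: `"survival"` keeps attempts with at least
#' one tip at `T`; `"size_window"` keeps attempts whose tip count falls in
#' `nT_target * (1 - window_frac) .. nT_target * (1 + window_frac)` (set
#' `window_frac = 0` for exact richness matching, feasible for small
#' targets). The seed is explicit — no hidden global state; one RNG stream
#' covers the whole attempt sequence, so batches are reproducible
#' end-to-end.
#'
#' @param params A [bd_params()] object.
#' @param T Simulation horizon, Myr.
#' @param seed Integer RNG seed.
#' @param conditioning One of `"none"`, `"survival"`, `"size_window"`.
#' @param nT_target Target extant richness (size_window only).
#' @param window_frac Relative half-width of the richness window
#'   (default 0.1).
#' @param max_events Cap on events per attempt (default 1e7), guarding
#'   runaway supercritical runs.
#' @param max_attempts Cap on rejection attempts (default 1e7). Exceeding
#'   it raises an error naming the acceptance probability estimated so far.
#' @return An object of class `"sim_config"`.
#' @examples
#' sim_config(bd_params(0.3, 0.2), T = 20, seed = 1, conditioning = "survival")
#' @export
sim_config <- function(params, T, seed,
                       conditioning = c("none", "survival", "size_window"),
                       nT_target = NULL, window_frac = 0.1,
                       max_events = 1e7, max_attempts = 1e7) {
  .check_params(params)
  conditioning <- match.arg(conditioning)
  stopifnot(is.numeric(T), length(T) == 1L, is.finite(T), T > 0,
            is.numeric(seed), length(seed) == 1L, is.finite(seed),
            max_events > 0, max_attempts > 0, window_frac >= 0)
  if (conditioning == "size_window") {
    stopifnot(!is.null(nT_target), nT_target >= 1)
    nT_lo <- max(1L, as.integer(floor(nT_target * (1 - window_frac))))
    nT_hi <- as.integer(ceiling(nT_target * (1 + window_frac)))
  } else {
    nT_lo <- nT_hi <- NA_integer_
  }
  structure(list(params = params, T = as.numeric(T), seed = as.integer(seed),
                 conditioning = conditioning,
                 nT_target = if (is.null(nT_target)) NA_integer_ else as.integer(nT_target),
                 window_frac = window_frac, nT_lo = nT_lo, nT_hi = nT_hi,
                 max_events = max_events, max_attempts = max_attempts),
            class = "sim_config")
}

.cond_code <- function(conditioning) {
  match(conditioning, c("none", "survival", "size_window")) - 1L
}

.wrap_tree <- function(raw, cfg) {
  structure(list(events = data.frame(
    time = raw$time,
    kind = ifelse(raw$kind == 1L, "speciation", "extinction"),
    lineage = raw$lineage,
    child = raw$child),
    tips = raw$tips,
    n_lineages = raw$n_lineages,
    T = cfg$T, params = cfg$params),
    class = "bd_tree")
}

#' Simulate a batch of birth-death trees
#'
#' Runs the Gillespie core until `n` trees satisfying the configured
#' conditioning have been accepted. Deterministic for a fixed
#' `cfg$seed` (the attempt index is folded into one RNG stream, not
#' re-seeded).
#'
#' @param cfg A [sim_config()] object.
#' @param n Number of accepted trees to return.
#' @return A list of `"bd_tree"` objects with attributes `attempts` (total
#'   attempts used) and `acceptance_rate`.
#' @examples
#' cfg <- sim_config(bd_params(0.3, 0.2), T = 10, seed = 42,
#'                   conditioning = "survival")
#' trees <- simulate_bd_trees(cfg, 5)
#' @export
simulate_bd_trees <- function(cfg, n) {
  if (!inherits(cfg, "sim_config")) stop("`cfg` must be a sim_config object")
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1, n == round(n))
  set.seed(cfg$seed)
  res <- bd_sim_batch_cpp(cfg$params$lambda, cfg$params$mu, cfg$T,
                          as.integer(n), .cond_code(cfg$conditioning),
                          if (is.na(cfg$nT_lo)) 0L else cfg$nT_lo,
                          if (is.na(cfg$nT_hi)) 0L else cfg$nT_hi,
                          cfg$max_events, cfg$max_attempts)
  out <- lapply(res$trees, .wrap_tree, cfg = cfg)
  attr(out, "attempts") <- res$attempts
  attr(out, "acceptance_rate") <- n / res$attempts
  attr(out, "config") <- cfg
  out
}

#' Simulate a single birth-death tree
#'
#' @inheritParams simulate_bd_trees
#' @return A `"bd_tree"` object: the full event history (time, kind,
#'   lineage, child), the lineage ids alive at `T`, and the scenario
#'   parameters.
#' @examples
#' cfg <- sim_config(bd_params(0.3, 0.2), T = 10, seed = 42,
#'                   conditioning = "survival")
#' tr <- simulate_bd_tree(cfg)
#' @export
simulate_bd_tree <- function(cfg) {
  simulate_bd_trees(cfg, 1L)[[1L]]
}

#' @export
print.bd_tree <- function(x, ...) {
  cat(sprintf(
    "Birth-death tree: %d lineages, %d events, %d tip(s) at T = %g Myr\n",
    x$n_lineages, nrow(x$events), length(x$tips), x$T))
  invisible(x)
}

# birth/death/surv_until bookkeeping shared by classification and Newick
.lineage_table <- function(tree) {
  n <- tree$n_lineages
  birth <- rep(NA_real_, n)
  death <- rep(Inf, n) # Inf = alive at T
  birth[1L] <- 0
  ev <- tree$events
  sp <- ev$kind == "speciation"
  birth[ev$child[sp]] <- ev$time[sp]
  death[ev$lineage[!sp]] <- ev$time[!sp]
  # latest time at which each lineage still has descendants reaching T
  # (Inf for tips: they are themselves extant at T)
  surv_until <- rep(-Inf, n)
  surv_until[tree$tips] <- Inf
  ev_sp <- ev[sp, , drop = FALSE]
  if (nrow(ev_sp) > 0) {
    for (i in rev(seq_len(nrow(ev_sp)))) { # reverse time: children first
      ch <- ev_sp$child[i]
      if (surv_until[ch] > -Inf && ev_sp$time[i] > surv_until[ev_sp$lineage[i]])
        surv_until[ev_sp$lineage[i]] <- ev_sp$time[i]
    }
  }
  data.frame(lineage = seq_len(n), birth = birth, death = death,
             surv_until = surv_until)
}

#' Classify lineages as surviving lineages or plesions
#'
#' A lineage is a *surviving lineage* if it is ancestral to at least one
#' tip at the present `T` (including being a tip itself); otherwise it is
#' a *plesion* — an extinct side branch. Speciation events on surviving
#' lineages that spawn non-surviving subtrees are plesion origins; their
#' per-Myr rate along the surviving lineages is the quantity the
#' push-of-the-past initial rate `(2 - s) lambda` predicts.
#'
#' @param tree A `"bd_tree"` object.
#' @param T Present time, Myr (defaults to the tree's own horizon).
#' @return A data frame with one row per lineage: `lineage`, `birth`,
#'   `death` (`Inf` for extant tips), `status` (`"surviving"` or
#'   `"plesion"`), `surv_until` (last time the lineage, while alive, still
#'   has descendants reaching `T`: `Inf` for extant tips, the birth time
#'   of the latest surviving child otherwise, `-Inf` for plesions), and
#'   `plesion_origins` (number of plesions spawned by this lineage).
#' @examples
#' cfg <- sim_config(bd_params(0.3, 0.2), T = 10, seed = 42,
#'                   conditioning = "survival")
#' table(classify_lineages(simulate_bd_tree(cfg))$status)
#' @export
classify_lineages <- function(tree, T = tree$T) {
  if (!inherits(tree, "bd_tree")) stop("`tree` must be a bd_tree object")
  lt <- .lineage_table(tree)
  surviving <- lt$surv_until > -Inf
  ev <- tree$events
  sp <- ev[ev$kind == "speciation", , drop = FALSE]
  porig <- integer(nrow(lt))
  if (nrow(sp) > 0) {
    is_plesion_child <- lt$surv_until[sp$child] == -Inf
    from_surviving <- surviving[sp$lineage]
    tb <- table(factor(sp$lineage[is_plesion_child & from_surviving],
                       levels = lt$lineage))
    porig <- as.integer(tb)
  }
  data.frame(lineage = lt$lineage, birth = lt$birth, death = lt$death,
             status = ifelse(surviving, "surviving", "plesion"),
             surv_until = lt$surv_until,
             plesion_origins = porig)
}

#' First crown-group origin time of a simulated tree
#'
#' The first time the tree has two coexisting species that both have
#' extant descendants — equivalently, the first (deepest) split of the
#' reconstructed extant-ancestry tree. A speciation event at time `tau`
#' qualifies when the new child's subtree reaches the present *and* the
#' mother still has surviving descent through something other than that
#' child (her own extant tip or a surviving child born after `tau`).
#'
#' @param tree A `"bd_tree"` object.
#' @return The first crown time in Myr, or `Inf` when fewer than two
#'   surviving lineages ever coexist (e.g. a single-tip tree).
#' @examples
#' cfg <- sim_config(bd_params(0.3, 0.2), T = 20, seed = 8,
#'                   conditioning = "size_window", nT_target = 5,
#'                   window_frac = 0)
#' first_crown_time(simulate_bd_tree(cfg))
#' @export
first_crown_time <- function(tree) {
  if (!inherits(tree, "bd_tree")) stop("`tree` must be a bd_tree object")
  lt <- .lineage_table(tree)
  ev <- tree$events
  sp <- ev[ev$kind == "speciation", , drop = FALSE]
  if (nrow(sp) == 0L) return(Inf)
  split <- lt$surv_until[sp$child] > -Inf & lt$surv_until[sp$lineage] > sp$time
  if (!any(split)) return(Inf)
  min(sp$time[split])
}

#' Export a simulated tree to Newick, retaining extinct tips
#'
#' Every speciation event becomes a bifurcation (the mother lineage
#' continues on one side); extinct lineages terminate at their extinction
#' time with their branch kept. Branch lengths are in Myr; tip labels
#' encode lineage id and fate, e.g. `L7_extant`, `L3_extinct`. The output
#' is parseable by standard Newick readers.
#'
#' @param tree A `"bd_tree"` object.
#' @return A single Newick string, semicolon-terminated.
#' @examples
#' cfg <- sim_config(bd_params(0.3, 0.2), T = 10, seed = 42,
#'                   conditioning = "survival")
#' to_newick(simulate_bd_tree(cfg))
#' @export
to_newick <- function(tree) {
  if (!inherits(tree, "bd_tree")) stop("`tree` must be a bd_tree object")
  lt <- .lineage_table(tree)
  ev <- tree$events
  sp <- ev[ev$kind == "speciation", , drop = FALSE]
  # speciation times/children per mother lineage, in time order
  kids <- split(sp[c("time", "child")], sp$lineage)
  end_time <- ifelse(is.infinite(lt$death), tree$T, lt$death)

  node <- function(lin, start) {
    ks <- kids[[as.character(lin)]]
    ks <- ks[ks$time > start, , drop = FALSE]
    if (!is.null(ks) && nrow(ks) > 0L) {
      tau <- ks$time[1L]
      paste0("(", node(lin, tau), ",", node(ks$child[1L], tau), "):",
             format(tau - start, digits = 12))
    } else {
      fate <- if (is.infinite(lt$death[lin])) "extant" else "extinct"
      paste0("L", lin, "_", fate, ":",
             format(end_time[lin] - start, digits = 12))
    }
  }
  body <- node(1L, 0)
  if (grepl("^L", body)) paste0("(", body, ");") else paste0(body, ";")
}

#' Empirical lineage-count distribution from simulated trees
#'
#' Tabulates, over a batch of trees sharing one configuration, either the
#' standing lineage count at `t` (`which = "n"`) or the number of time-`t`
#' lineages ancestral to at least one tip at `T` (`which = "m"`). This is
#' the Monte Carlo counterpart of [conditional_size_distribution()] /
#' [surviving_count_distribution()].
#'
#' @param trees A list of `"bd_tree"` objects (as returned by
#'   [simulate_bd_trees()]).
#' @param t Evaluation time, Myr.
#' @param which `"n"` for standing diversity, `"m"` for surviving-ancestor
#'   counts.
#' @return A [bd_distribution()] of empirical frequencies.
#' @export
empirical_distribution <- function(trees, t, which = c("n", "m")) {
  which <- match.arg(which)
  if (length(trees) == 0L) stop("empty tree collection")
  counts <- lineage_counts(trees, t, which)
  tb <- table(factor(counts, levels = seq(min(counts), max(counts))))
  bd_distribution(min(counts), log(as.numeric(tb)) - log(length(counts)))
}

#' Per-tree lineage counts at a time point
#'
#' @inheritParams empirical_distribution
#' @return Integer vector, one count per tree.
#' @export
lineage_counts <- function(trees, t, which = c("n", "m")) {
  which <- match.arg(which)
  if (length(trees) == 0L) stop("empty tree collection")
  T <- trees[[1L]]$T
  stopifnot(t >= 0, t <= T)
  raw <- lapply(trees, function(tr) list(
    time = tr$events$time,
    kind = ifelse(tr$events$kind == "speciation", 1L, 0L),
    lineage = tr$events$lineage, child = tr$events$child,
    tips = tr$tips, n_lineages = tr$n_lineages))
  bd_count_at_cpp(raw, t, T, which == "m")
}
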