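#' Synthetic expert-panel scenario
#'
#' Parameters of a simulated Delphi panel: a bank of items rated on a
#' Likert scale by a first-round panel, of which a subset returns for the
#' second round (attrition). Ratings follow a discretized latent-trait
#' model: expert *j*'s rating of item *i* is
#' \deqn{r_{ij} = \mathrm{clamp}(\mathrm{round}(\mu_i + \sigma_i
#'   \varepsilon_{ij} + \delta_j),\ \mathrm{scale})}
#' with item dispersion \eqn{\sigma_i}, a persistent rater leniency
#' effect \eqn{\delta_j \sim N(0, \tau^2)}, and the item location
#' \eqn{\mu_i} calibrated so that the marginal endorsement probability
#' `P(rating >= 4)` equals the target `endorsement_prob[i]` exactly:
#' since the latent score is marginally normal with SD
#' \eqn{s = \sqrt{\sigma_i^2 + \tau^2}}, the calibration is
#' \eqn{\mu_i = 3.5 + s\,\Phi^{-1}(p_i)}. One latent location moves
#' I-CVI and Aiken's V together, mirroring their empirical coupling in
#' real panels.
#'
#' Default panel sizes (36 experts in round 1, 30 in round 2) match a
#' typical national Delphi study; dispersion defaults
#' (`item_sd = 0.9`, `rater_sd = 0.4`, total latent SD about one scale
#' point) give realistic expert disagreement on a 5-point scale.
#'
#' @param n_items Number of items in the bank.
#' @param endorsement_prob Target `P(rating >= 4)` per item (recycled).
#' @param n_experts_round1,n_experts_round2 Panel sizes; round 2 must
#'   not exceed round 1.
#' @param comprehension_prob Target `P(rating >= 4)` on the
#'   comprehensibility dimension (recycled); default 0.85, a mostly
#'   clear item bank.
#' @param item_sd Latent dispersion \eqn{\sigma_i} (recycled).
#' @param rater_sd SD \eqn{\tau} of the persistent rater effect.
#' @param seed Global RNG seed; per-item, per-expert substreams are
#'   derived from it so adding items does not perturb existing draws.
#' @param dropouts Character vector of expert ids absent from round 2;
#'   default, the highest-numbered experts.
#' @param scale_min,scale_max Likert scale bounds.
#' @return An object of class `panel_scenario`.
#' @export
panel_scenario <- function(n_items = 114,
                           endorsement_prob = 0.7,
                           n_experts_round1 = 36,
                           n_experts_round2 = 30,
                           comprehension_prob = 0.85,
                           item_sd = 0.9,
                           rater_sd = 0.4,
                           seed = 1L,
                           dropouts = NULL,
                           scale_min = 1L, scale_max = 5L) {
  n_items <- assert_count(n_items, "n_items", 1L)
  n1 <- assert_count(n_experts_round1, "n_experts_round1", 1L)
  n2 <- assert_count(n_experts_round2, "n_experts_round2", 0L)
  if (n2 > n1) stop("round-2 panel cannot exceed round 1", call. = FALSE)
  p <- rep_len(endorsement_prob, n_items)
  pc <- rep_len(comprehension_prob, n_items)
  if (any(p < 0 | p > 1) || any(pc < 0 | pc > 1)) {
    stop("endorsement probabilities must lie in [0, 1]", call. = FALSE)
  }
  sig <- rep_len(item_sd, n_items)
  if (any(sig <= 0) || rater_sd < 0) {
    stop("dispersions must be positive", call. = FALSE)
  }
  experts <- sprintf("e%02d", seq_len(n1))
  dropouts <- dropouts %||% utils::tail(experts, n1 - n2)
  if (!all(dropouts %in% experts) || (n1 - length(dropouts)) != n2) {
    stop("`dropouts` must name exactly the round-1 experts absent in round 2",
         call. = FALSE)
  }
  structure(
    list(n_items = n_items, endorsement_prob = p, comprehension_prob = pc,
         item_sd = sig, rater_sd = rater_sd,
         n_experts_round1 = n1, n_experts_round2 = n2,
         experts = experts, dropouts = dropouts,
         seed = as.integer(seed),
         scale_min = as.integer(scale_min), scale_max = as.integer(scale_max)),
    class = "panel_scenario"
  )
}

#' @export
print.panel_scenario <- function(x, ...) {
  cat(sprintf("<panel_scenario> %d items, experts %d -> %d, seed %d\n",
              x$n_items, x$n_experts_round1, x$n_experts_round2, x$seed))
  invisible(x)
}

# latent location giving P(rating >= top box) = p, for total latent SD s;
# rating >= 4 iff latent >= 3.5 on the default scale
calibrate_mu <- function(p, s, threshold = 3.5) {
  threshold + s * stats::qnorm(pmin(pmax(p, 1e-12), 1 - 1e-12))
}

# category probabilities of the clamped, rounded latent-normal rating
rating_probs <- function(mu, s, scale_min = 1L, scale_max = 5L) {
  cats <- scale_min:scale_max
  upper <- c(cats[-length(cats)] + 0.5, Inf)
  lower <- c(-Inf, utils::head(upper, -1))
  stats::pnorm(upper, mu, s) - stats::pnorm(lower, mu, s)
}

# model-implied Aiken's V for a latent location mu and total SD s
expected_v <- function(mu, s, scale_min = 1L, scale_max = 5L) {
  pr <- rating_probs(mu, s, scale_min, scale_max)
  (sum((scale_min:scale_max) * pr) - scale_min) / (scale_max - scale_min)
}

# substream seed for one (item, round, dimension) stream; item 0 is the
# rater-effect stream. A Lehmer step breaks the additive lattice so
# replicate panels (seed, seed + 1, ...) land on well-separated streams.
stream_seed <- function(seed, item, round = 0L, dim_code = 0L) {
  h <- (abs(seed) %% 65011 * 2654435 + item * 7919 +
          round * 104729 + dim_code * 333331) %% 2147483647
  (h * 48271) %% 2147483647
}

# rnorm from a dedicated stream, leaving the caller's RNG untouched;
# raters are drawn sequentially from one Mersenne-Twister stream so
# within-panel draws are iid
stream_norm <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  stats::rnorm(n)
}

#' Generate a two-round synthetic ratings table
#'
#' Draws every expert-by-item rating for both dimensions and both rounds
#' under the scenario's latent model (see [panel_scenario()]). Output is
#' the canonical long ratings format accepted by the whole pipeline.
#' Round 2 contains only the experts who did not drop out; a fixed seed
#' yields byte-identical output, and each (item, expert) cell has its own
#' derived substream, so extending the item bank leaves existing draws
#' unchanged.
#'
#' @param scenario A [panel_scenario()].
#' @param rounds Which rounds to generate (default both).
#' @return Validated ratings tibble (columns
#'   `round,item_id,expert_id,dimension,rating`).
#' @export
generate_panel <- function(scenario, rounds = c(1L, 2L)) {
  stopifnot(inherits(scenario, "panel_scenario"))
  sc <- scenario
  s_tot <- sqrt(sc$item_sd^2 + sc$rater_sd^2)
  thr <- sc$scale_max - 1.5  # rating >= (scale_max - 1) iff latent >= this
  mu_rel <- calibrate_mu(sc$endorsement_prob, s_tot, thr)
  mu_com <- calibrate_mu(sc$comprehension_prob, s_tot, thr)

  delta <- sc$rater_sd * stream_norm(stream_seed(sc$seed, 0L),
                                     length(sc$experts))

  rows <- vector("list", length(rounds))
  for (ri in seq_along(rounds)) {
    r <- rounds[ri]
    active <- if (r == 1L) sc$experts else setdiff(sc$experts, sc$dropouts)
    jidx <- match(active, sc$experts)
    n_cells <- sc$n_items * length(active)
    item <- rep(seq_len(sc$n_items), each = length(active))
    expert <- rep(jidx, times = sc$n_items)
    draw_dim <- function(mu, dim_code) {
      # one stream per (item, round, dimension); all raters' noise is
      # drawn from it at their roster position, so the draws are iid
      # within a panel and stable under both attrition and bank growth
      eps <- unlist(lapply(seq_len(sc$n_items), function(i) {
        stream_norm(stream_seed(sc$seed, i, r, dim_code),
                    length(sc$experts))[jidx]
      }), use.names = FALSE)
      latent <- mu[item] + sc$item_sd[item] * eps + delta[expert]
      pmin(pmax(round(latent), sc$scale_min), sc$scale_max)
    }
    rows[[ri]] <- tibble::tibble(
      round = rep(as.integer(r), 2L * n_cells),
      item_id = rep(sprintf("i%03d", item), 2L),
      expert_id = rep(sc$experts[expert], 2L),
      dimension = rep(c("relevance", "comprehensibility"), each = n_cells),
      rating = as.integer(c(draw_dim(mu_rel, 1L), draw_dim(mu_com, 2L)))
    )
  }
  validate_ratings(dplyr::bind_rows(rows),
                   scale_min = sc$scale_min, scale_max = sc$scale_max)
}

#' Scenario calibrated to target (I-CVI, V) pairs
#'
#' Builds a [panel_scenario()] whose model-implied I-CVI and Aiken's V
#' match given per-item targets — e.g. the rows of a published validity
#' table — so simulated panels recover them up to Monte-Carlo error. The
#' endorsement probability is set to the target CVI directly; the item
#' dispersion is then found by root-finding so the model-implied V (see
#' the latent model in [panel_scenario()]) hits the target V.
#'
#' Feasibility: with all endorsing ratings at least 4 and the rest at
#' most 3 (on a 1-5 scale), a CVI of `p` forces the mean rating into
#' `[1 + 3p, 3 + 2p]`, i.e. `V` into `[3p/4, (1 + p)/2]`. Pairs outside
#' that band (such as CVI 1 with V 0.1) are rejected.
#'
#' @param cvi,v Numeric vectors of per-item targets in `[0, 1]`.
#' @param n_experts Panel size to simulate (single round; default 30).
#' @param rater_sd,seed,scale_min,scale_max Passed to [panel_scenario()].
#' @return A single-round [panel_scenario()] (round 2 panel equal to
#'   round 1) with per-item `endorsement_prob` and `item_sd`.
#' @export
scenario_from_table <- function(cvi, v, n_experts = 30, rater_sd = 0.4,
                                seed = 1L, scale_min = 1L, scale_max = 5L) {
  stopifnot(length(cvi) == length(v))
  if (any(cvi < 0 | cvi > 1) || any(v < 0 | v > 1)) {
    stop("targets must lie in [0, 1]", call. = FALSE)
  }
  lo <- 3 * cvi / 4
  hi <- (1 + cvi) / 2
  bad <- which(v < lo - 1e-9 | v > hi + 1e-9)
  if (length(bad) > 0) {
    stop(sprintf("infeasible (CVI, V) target: CVI %.3f forces V into [%.3f, %.3f], got %.3f",
                 cvi[bad[1]], lo[bad[1]], hi[bad[1]], v[bad[1]]),
         call. = FALSE)
  }
  thr <- scale_max - 1.5
  solve_sd <- function(p, v_target) {
    f <- function(s_tot) {
      expected_v(calibrate_mu(p, s_tot, thr), s_tot, scale_min, scale_max) -
        v_target
    }
    grid <- exp(seq(log(0.05), log(8), length.out = 60))
    vals <- vapply(grid, f, numeric(1))
    flip <- which(diff(sign(vals)) != 0)
    if (length(flip) > 0) {
      stats::uniroot(f, c(grid[flip[1]], grid[flip[1] + 1]), tol = 1e-8)$root
    } else {
      best <- which.min(abs(vals))
      if (abs(vals[best]) > 0.005) {
        stop(sprintf("cannot calibrate dispersion for CVI %.3f with V %.3f",
                     p, v_target), call. = FALSE)
      }
      grid[best]
    }
  }
  s_tot <- mapply(solve_sd, cvi, v)
  # keep the rater effect a minority share of the smallest total dispersion
  # so the per-item sd stays positive and the calibration exact
  rater_sd <- min(rater_sd, 0.5 * min(s_tot))
  item_sd <- sqrt(s_tot^2 - rater_sd^2)
  panel_scenario(n_items = length(cvi), endorsement_prob = cvi,
                 n_experts_round1 = n_experts, n_experts_round2 = n_experts,
                 item_sd = item_sd, rater_sd = rater_sd, seed = seed,
                 scale_min = scale_min, scale_max = scale_max)
}
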