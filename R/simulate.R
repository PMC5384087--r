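#' Simulate a birth-death chronogram
#'
#' Forward simulation from a crown pair under exponentially time-dependent
#' speciation and extinction rates (`lambda(t) = lambda0 exp(alpha t)`,
#' `mu(t) = mu0 exp(beta t)`, `t` in my before present), using thinning for
#' the time-varying case. Extinct lineages are pruned for the reconstructed
#' tree; incomplete sampling drops each surviving tip with probability
#' `1 - f`. Whole-clade extinction (or fewer than two sampled survivors)
#' triggers resimulation, up to `max_attempts` times.
#'
#' Either `crown_age` (fixed duration) or `n_tips` (stop at the first moment
#' the extant count reaches `n_tips`; constant rates only) must be given.
#'
#' @inheritParams rate_at
#' @param crown_age Crown age in my (forward duration of the simulation).
#' @param n_tips Target number of extant tips (alternative to `crown_age`).
#' @param f Sampling fraction in `(0, 1]`.
#' @param seed Integer seed; the result is bit-reproducible given
#'   `(seed, parameters)`.
#' @param max_attempts Resimulation cap (default 1000).
#' @param return_full Also return the tree with extinct lineages.
#' @return A `phylo` chronogram with tips `sp0001, ...`; attributes
#'   `attempts` (resimulations used) and, if requested, `full_tree`.
#' @export
simulate_bd_tree <- function(lambda0, alpha = 0, mu0 = 0, beta = 0,
                             crown_age = NULL, n_tips = NULL, f = 1,
                             seed = 1L, max_attempts = 1000L,
                             return_full = FALSE) {
  stopifnot(lambda0 > 0, mu0 >= 0, f > 0, f <= 1)
  if (is.null(crown_age) == is.null(n_tips)) {
    stop("give exactly one of crown_age or n_tips", call. = FALSE)
  }
  if (!is.null(n_tips) && (alpha != 0 || beta != 0)) {
    stop("n_tips conditioning requires constant rates (alpha = beta = 0)",
         call. = FALSE)
  }
  with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      sim <- bd_forward_once(lambda0, alpha, mu0, beta, crown_age, n_tips)
      if (is.null(sim)) next
      extant <- sim$extant
      if (f < 1) extant <- extant & (stats::runif(length(extant)) < f)
      if (sum(extant & sim$is_tip) < 2L) next
      full <- bd_sim_to_phylo(sim)
      keep <- sim$tip_label[sim$is_tip & extant]
      recon <- ape::keep.tip(full, keep)
      recon$tip.label <- sprintf("sp%04d", seq_len(ape::Ntip(recon)))
      attr(recon, "attempts") <- attempt
      if (return_full) attr(recon, "full_tree") <- full
      return(recon)
    }
    stop("whole-clade extinction in every one of ", max_attempts,
         " attempts (mu too close to or above lambda?)", call. = FALSE)
  })
}

# one forward pass; returns NULL on whole-clade extinction before the end
bd_forward_once <- function(lambda0, alpha, mu0, beta, crown_age, n_tips) {
  fixed_T <- !is.null(crown_age)
  cap <- if (fixed_T) NULL else n_tips
  # lineage bookkeeping (grown geometrically)
  N <- 64L
  parent <- integer(N); birth <- numeric(N); death <- numeric(N)
  child1 <- integer(N); child2 <- integer(N); alive <- logical(N)
  n_lin <- 2L
  parent[1:2] <- 0L; birth[1:2] <- 0; alive[1:2] <- TRUE
  s <- 0
  lam_fwd <- function(s_now, T_) lambda0 * exp(alpha * (T_ - s_now))
  mu_fwd <- function(s_now, T_) mu0 * exp(beta * (T_ - s_now))
  T_ <- if (fixed_T) crown_age else Inf
  repeat {
    k <- sum(alive)
    if (k == 0L) return(NULL)
    if (!fixed_T && k >= cap) {
      # place the present strictly between the nth birth and the next event
      # so that no pendant branch has zero length
      dt_next <- stats::rexp(1, k * (lambda0 + mu0))
      T_ <- s + stats::runif(1) * dt_next
      break
    }
    if (fixed_T) {
      # rate bound over [s, T]: exponential rates are monotone in time
      lmax <- max(lam_fwd(s, T_), lam_fwd(T_, T_))
      mmax <- max(mu_fwd(s, T_), mu_fwd(T_, T_))
    } else {
      lmax <- lambda0; mmax <- mu0
    }
    R <- k * (lmax + mmax)
    if (R <= 0) { if (fixed_T) break else return(NULL) }
    s_prop <- s + stats::rexp(1, R)
    if (fixed_T && s_prop >= T_) break
    s <- s_prop
    lam_now <- if (fixed_T) lam_fwd(s, T_) else lambda0
    mu_now <- if (fixed_T) mu_fwd(s, T_) else mu0
    if (stats::runif(1) >= (lam_now + mu_now) / (lmax + mmax)) next # thinned
    who_idx <- which(alive)
    L <- who_idx[sample.int(length(who_idx), 1L)]
    if (stats::runif(1) < lam_now / (lam_now + mu_now)) {
      # speciation: L ends, two daughters born
      if (n_lin + 2L > N) {
        add <- N; N <- N * 2L
        parent <- c(parent, integer(add)); birth <- c(birth, numeric(add))
        death <- c(death, numeric(add)); child1 <- c(child1, integer(add))
        child2 <- c(child2, integer(add)); alive <- c(alive, logical(add))
      }
      death[L] <- s; alive[L] <- FALSE
      c1 <- n_lin + 1L; c2 <- n_lin + 2L; n_lin <- n_lin + 2L
      parent[c(c1, c2)] <- L; birth[c(c1, c2)] <- s
      alive[c(c1, c2)] <- TRUE
      child1[L] <- c1; child2[L] <- c2
    } else {
      death[L] <- s; alive[L] <- FALSE
    }
  }
  idx <- seq_len(n_lin)
  is_tip <- child1[idx] == 0L
  death[which(alive[idx])] <- T_
  extant <- alive[idx]
  if (sum(extant) < 2L) return(NULL)
  list(parent = parent[idx], birth = birth[idx], death = death[idx],
       child1 = child1[idx], child2 = child2[idx],
       is_tip = is_tip, extant = extant,
       tip_label = ifelse(is_tip, sprintf("L%d", idx), NA_character_),
       T_ = T_)
}

bd_sim_to_phylo <- function(sim) {
  str_of <- function(L) {
    len <- sim$death[L] - sim$birth[L]
    if (sim$child1[L] == 0L) {
      sprintf("%s:%.10f", sim$tip_label[L], len)
    } else {
      sprintf("(%s,%s):%.10f", str_of(sim$child1[L]), str_of(sim$child2[L]), len)
    }
  }
  txt <- sprintf("(%s,%s);", str_of(1L), str_of(2L))
  ape::read.tree(text = txt)
}

#' Simulate a Brownian-motion trait under lambda/delta scaling
#'
#' Draws tip values from the multivariate normal implied by the
#' lambda/delta-transformed phylogenetic covariance.
#'
#' @inheritParams bm_loglik
#' @param seed Integer seed.
#' @return Named numeric vector of tip values.
#' @export
simulate_bm_trait <- function(tree, sigma2, root_state = 0, lambda = 1,
                              delta = 1, seed = 1L) {
  if (sigma2 < 0) stop("sigma2 must be >= 0", call. = FALSE)
  n <- ape::Ntip(tree)
  if (sigma2 == 0) {
    x <- rep(root_state, n)
    names(x) <- tree$tip.label
    return(x)
  }
  V <- transformed_vcv(tree, lambda, delta) * sigma2
  ch <- chol(V)
  with_seed(seed, {
    z <- stats::rnorm(n)
    x <- root_state + as.numeric(t(ch) %*% z)
    names(x) <- tree$tip.label
    x
  })
}

#' Simulate a DEC range history along a chronogram
#'
#' Anagenesis is simulated along each branch by event sampling from the
#' slice-specific rates (dispersal gains and extirpation losses);
#' cladogenesis draws one scenario from the DEC inheritance law at every
#' node (sympatry for single-area ranges; subset sympatry or vicariance,
#' uniformly among scenarios and daughter orderings, for widespread ranges).
#' A lineage that loses its last area falls into the null range and is
#' recorded as extirpated (with `on_null = "resimulate"` the whole history
#' is redrawn, up to 1000 attempts).
#'
#' @inheritParams dec_loglik
#' @param root_range Area string for the root range; `NULL` samples it
#'   uniformly from the observable states.
#' @param seed Integer seed.
#' @param on_null `"record"` (default) or `"resimulate"`.
#' @return List: `tip_ranges` (named area strings; `"0"` for extirpated
#'   tips), `node_ranges` (all nodes), `events` (tibble: branch child node,
#'   age, type, area), `extirpated` (tip labels), `root_range`.
#' @export
simulate_dec_history <- function(tree, d, e,
                                 schedule = default_dispersal_schedule(),
                                 max_range_size = 4L, root_range = NULL,
                                 seed = 1L, on_null = c("record", "resimulate")) {
  on_null <- match.arg(on_null)
  if (d < 0 || e < 0) stop("d and e must be >= 0", call. = FALSE)
  areas <- schedule$areas
  k <- n_areas(areas)
  bit <- bitwShiftL(1L, seq_len(k) - 1L)
  states <- enumerate_states(areas, max_range_size)
  ages <- node_ages(tree)
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  root <- n + 1L
  root_mask <- if (is.null(root_range)) NA_integer_ else parse_range(root_range, areas)
  boundaries <- schedule$boundaries
  mult <- schedule$multipliers
  with_seed(seed, {
    for (attempt in seq_len(1000L)) {
      clado_draw_cache$draws <- list()
      node_mask <- integer(nn)
      events <- list()
      rm <- if (is.na(root_mask)) {
        obs <- states$mask[states$size > 0]
        obs[sample.int(length(obs), 1L)]
      } else root_mask
      node_mask[root] <- rm
      ok <- TRUE
      # pre-order: draw cladogenesis at each internal node, then anagenesis
      # down each daughter branch
      for (e_idx in rev(ape::postorder(tree))) {
        pnode <- tree$edge[e_idx, 1L]; cnode <- tree$edge[e_idx, 2L]
        S <- node_mask[pnode]
        # cladogenetic daughter state at the top of this branch
        top <- if (S == 0L) 0L else draw_daughter(S, pnode, cnode, tree, bit)
        res <- anagenesis_branch(top, ages[pnode], ages[cnode], d, e,
                                 boundaries, mult, bit, max_range_size)
        node_mask[cnode] <- res$mask
        if (length(res$age) > 0L) {
          events[[length(events) + 1L]] <-
            tibble::tibble(child_node = cnode, age = res$age,
                           type = res$type, area = unclass(areas)[res$area])
        }
      }
      tips <- node_mask[seq_len(n)]
      if (on_null == "resimulate" && any(tips == 0L)) next
      ev <- if (length(events) > 0L) dplyr::bind_rows(events) else
        tibble::tibble(child_node = integer(0), age = numeric(0),
                       type = character(0), area = character(0))
      tip_ranges <- mask_to_label(tips, areas)
      names(tip_ranges) <- tree$tip.label
      return(list(
        tip_ranges = tip_ranges,
        node_ranges = stats::setNames(mask_to_label(node_mask, areas),
                                      c(tree$tip.label,
                                        paste0("node_", (n + 1L):nn))),
        events = ev,
        extirpated = tree$tip.label[tips == 0L],
        root_range = mask_to_label(rm, areas),
        attempts = attempt
      ))
    }
    stop("range history fell to the null range in every attempt", call. = FALSE)
  })
}

# sample one daughter state from the cladogenesis law; daughters of a node
# are drawn jointly once (cached on first visit) so both branches agree
clado_draw_cache <- new.env(parent = emptyenv())
draw_daughter <- function(S, pnode, cnode, tree, bit) {
  key <- as.character(pnode)
  drawn <- clado_draw_cache$draws[[key]]
  if (is.null(drawn)) {
    occ <- bit[bitwAnd(S, bit) > 0L]
    if (length(occ) == 1L) {
      pair <- c(S, S)
    } else {
      i <- occ[sample.int(length(occ), 1L)]
      vic <- stats::runif(1) < 0.5
      small <- i
      big <- if (vic) S - i else S
      pair <- if (stats::runif(1) < 0.5) c(small, big) else c(big, small)
    }
    kids <- tree$edge[tree$edge[, 1L] == pnode, 2L]
    drawn <- stats::setNames(pair, as.character(kids))
    if (is.null(clado_draw_cache$draws)) clado_draw_cache$draws <- list()
    clado_draw_cache$draws[[key]] <- drawn
  }
  out <- drawn[[as.character(cnode)]]
  # drop the cache entry once both daughters have been served
  clado_draw_cache$draws[[key]] <-
    drawn[setdiff(names(drawn), as.character(cnode))]
  if (length(clado_draw_cache$draws[[key]]) == 0L) {
    clado_draw_cache$draws[[key]] <- NULL
  }
  out
}

# Gillespie simulation of gains/losses from parent_age down to child_age
anagenesis_branch <- function(mask, parent_age, child_age, d, e,
                              boundaries, mult, bit, max_range_size) {
  ev_age <- numeric(0); ev_type <- character(0); ev_area <- integer(0)
  a <- parent_age
  k <- length(bit)
  while (a > child_age + 1e-12 && mask != 0L) {
    sl <- findInterval(-(a - 1e-12), -boundaries, rightmost.closed = TRUE)
    sl <- min(max(sl, 1L), length(boundaries) - 1L)
    seg_end <- max(child_age, boundaries[sl + 1L])
    m <- mult[[sl]]
    occ <- which(bitwAnd(mask, bit) > 0L)
    gain_rate <- if (length(occ) < max_range_size) {
      vapply(seq_len(k), function(j) {
        if (j %in% occ) 0 else d * sum(m[occ, j])
      }, numeric(1))
    } else numeric(k)
    loss_rate <- ifelse(seq_len(k) %in% occ, e, 0)
    R <- sum(gain_rate) + sum(loss_rate)
    if (R <= 0) { a <- seg_end; next }
    dt <- stats::rexp(1, R)
    if (a - dt <= seg_end) { a <- seg_end; next }
    a <- a - dt
    probs <- c(gain_rate, loss_rate)
    pick <- sample.int(2L * k, 1L, prob = probs)
    if (pick <= k) {
      mask <- bitwOr(mask, bit[pick])
      ev_age <- c(ev_age, a); ev_type <- c(ev_type, "gain"); ev_area <- c(ev_area, pick)
    } else {
      j <- pick - k
      mask <- mask - bit[j]
      ev_age <- c(ev_age, a); ev_type <- c(ev_type, "loss"); ev_area <- c(ev_area, j)
    }
  }
  list(mask = mask, age = ev_age, type = ev_type, area = ev_area)
}

#' Assemble a species table from simulated components
#'
#' Builds (and optionally writes) a species CSV in the package's standard
#' schema: `species, previous_name, molecular, morphology, areas, elev_mean,
#' elev_low, elev_high`.
#'
#' @inheritParams mrca_clade
#' @param elev_mean,elev_low,elev_high Named numeric vectors (m) over tips.
#' @param ranges Named area strings over tips.
#' @param molecular,morphology Named logical vectors (default all `TRUE`).
#' @param areas The [area_system()] used to validate range letters.
#' @param path Optional CSV output path.
#' @return Tibble in the species-table schema.
#' @export
make_species_table <- function(tree, elev_mean, elev_low, elev_high, ranges,
                               molecular = NULL, morphology = NULL,
                               areas = area_system(), path = NULL) {
  tips <- tree$tip.label
  for (v in list(elev_mean, elev_low, elev_high, ranges)) {
    if (!all(tips %in% names(v))) {
      stop("tip sets of tree and components do not match", call. = FALSE)
    }
  }
  parse_range(unname(ranges[tips]), areas) # validates letters
  molecular <- molecular %||% stats::setNames(rep(TRUE, length(tips)), tips)
  morphology <- morphology %||% stats::setNames(rep(TRUE, length(tips)), tips)
  out <- tibble::tibble(
    species = tips,
    previous_name = NA_character_,
    molecular = unname(molecular[tips]),
    morphology = unname(morphology[tips]),
    areas = unname(ranges[tips]),
    elev_mean = unname(elev_mean[tips]),
    elev_low = unname(elev_low[tips]),
    elev_high = unname(elev_high[tips])
  )
  if (any(out$elev_low > out$elev_mean | out$elev_mean > out$elev_high)) {
    stop("elevational ordering violated (need low <= mean <= high)", call. = FALSE)
  }
  if (!is.null(path)) readr::write_csv(out, path)
  out
}

#' Replace a tip by a simulated clade (rate-shift scenarios)
#'
#' Grafts `clade` (an ultrametric tree with crown age less than the pendant
#' branch of `tip`) in place of `tip`, preserving ultrametricity: the stem
#' of the clade takes up the remaining pendant length.
#'
#' @inheritParams mrca_clade
#' @param tip Tip label to replace.
#' @param clade Ultrametric `phylo` to graft (tip labels must not clash).
#' @return A `phylo` chronogram.
#' @export
graft_clade <- function(tree, tip, clade) {
  stopifnot(tip %in% tree$tip.label)
  if (any(clade$tip.label %in% tree$tip.label)) {
    clade$tip.label <- paste0(tip, "_", clade$tip.label)
  }
  edge_i <- which(tree$edge[, 2L] == match(tip, tree$tip.label))
  pend <- tree$edge.length[edge_i]
  crown <- max(ape::node.depth.edgelength(clade))
  if (crown >= pend) {
    stop("clade crown age must be smaller than the pendant branch of '",
         tip, "'", call. = FALSE)
  }
  clade_txt <- sub(";\\s*$", "", ape::write.tree(clade, digits = 12))
  host_txt <- ape::write.tree(tree, digits = 12)
  pat <- paste0(gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", tip), ":[0-9.eE+-]+")
  rep_txt <- sprintf("%s:%.10f", clade_txt, pend - crown)
  out_txt <- sub(pat, rep_txt, host_txt)
  parse_newick(out_txt)
}
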