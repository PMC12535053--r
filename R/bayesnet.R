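# Discrete Bayesian network machinery for the membership model: quintile
# discretization, score-based hill-climbing structure search with the BIC,
# maximum-likelihood CPTs with light smoothing, and exact posterior
# computation for the source-indicator node (all other nodes observed, so
# the posterior only involves the source node's Markov blanket).

bn_discretize <- function(values, schema, covariates, bins) {
  map <- list()
  out <- list()
  for (nm in covariates) {
    v <- values[[nm]]
    if (schema_kind(schema, nm) == "binary") {
      out[[nm]] <- as.integer(v) + 1L
      map[[nm]] <- list(kind = "binary", levels = 2L)
    } else {
      qs <- unique(stats::quantile(v, probs = seq_len(bins - 1) / bins,
                                   names = FALSE, type = 7))
      cutpts <- c(-Inf, qs, Inf)
      out[[nm]] <- as.integer(cut(v, cutpts, labels = FALSE))
      map[[nm]] <- list(kind = "continuous", breaks = cutpts,
                        levels = length(cutpts) - 1L)
    }
  }
  list(codes = out, map = map)
}

# log-likelihood + dimension of one node given a parent set, from integer
# level codes; cached by caller
bn_family_score <- function(codes, nlev, node, parents, n, cache) {
  key <- paste0(node, "|", paste(sort(parents), collapse = ","))
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  x <- codes[[node]]
  r <- nlev[[node]]
  if (length(parents) == 0L) {
    cnt <- tabulate(x, r)
    ll <- sum(cnt[cnt > 0] * log(cnt[cnt > 0] / n))
    q <- 1L
  } else {
    pa_code <- integer(n)
    mult <- 1L
    for (p in parents) {
      pa_code <- pa_code + (codes[[p]] - 1L) * mult
      mult <- mult * nlev[[p]]
    }
    q <- mult
    idx <- pa_code * r + x  # in 1..r*q
    cnt <- tabulate(idx, r * q)
    M <- matrix(cnt, nrow = r)
    tot <- colSums(M)
    pos <- M > 0
    ll <- sum(M[pos] * log(M[pos] / rep(tot, each = r)[pos]))
  }
  sc <- ll - 0.5 * log(n) * (r - 1) * q
  cache[[key]] <- sc
  sc
}

bn_has_path <- function(adj, from, to) {
  # DFS: is there a directed path from 'from' to 'to'?
  seen <- logical(nrow(adj))
  stack <- from
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v == to) return(TRUE)
    if (seen[v]) next
    seen[v] <- TRUE
    stack <- c(stack, which(adj[v, ] == 1L))
  }
  FALSE
}

bn_hill_climb <- function(codes, nlev, nodes, n, max_parents, seed,
                          restarts, init_prob, cache) {
  p <- length(nodes)
  total_score <- function(adj) {
    sum(vapply(seq_len(p), function(j)
      bn_family_score(codes, nlev, nodes[j], nodes[adj[, j] == 1L], n, cache),
      0))
  }
  climb <- function(adj) {
    node_sc <- vapply(seq_len(p), function(j)
      bn_family_score(codes, nlev, nodes[j], nodes[adj[, j] == 1L], n, cache), 0)
    repeat {
      best <- list(delta = 1e-8, move = NULL)
      for (i in seq_len(p)) for (j in seq_len(p)) {
        if (i == j) next
        if (adj[i, j] == 0L) {                       # add i -> j
          if (sum(adj[, j]) >= max_parents) next
          if (bn_has_path(adj, j, i)) next
          ns <- bn_family_score(codes, nlev, nodes[j],
                                nodes[c(which(adj[, j] == 1L), i)], n, cache)
          d <- ns - node_sc[j]
          if (d > best$delta)
            best <- list(delta = d, move = c("add", i, j), new = ns)
        } else {                                     # delete or reverse i -> j
          pa_del <- setdiff(which(adj[, j] == 1L), i)
          ns_del <- bn_family_score(codes, nlev, nodes[j], nodes[pa_del], n, cache)
          d <- ns_del - node_sc[j]
          if (d > best$delta)
            best <- list(delta = d, move = c("del", i, j), new = ns_del)
          if (sum(adj[, i]) < max_parents) {
            adj2 <- adj; adj2[i, j] <- 0L
            if (!bn_has_path(adj2, i, j)) {
              ns_i <- bn_family_score(codes, nlev, nodes[i],
                                      nodes[c(which(adj[, i] == 1L), j)], n, cache)
              d <- (ns_del - node_sc[j]) + (ns_i - node_sc[i])
              if (d > best$delta)
                best <- list(delta = d, move = c("rev", i, j),
                             new = c(ns_del, ns_i))
            }
          }
        }
      }
      if (is.null(best$move)) break
      i <- as.integer(best$move[2]); j <- as.integer(best$move[3])
      if (best$move[1] == "add") {
        adj[i, j] <- 1L; node_sc[j] <- best$new
      } else if (best$move[1] == "del") {
        adj[i, j] <- 0L; node_sc[j] <- best$new
      } else {
        adj[i, j] <- 0L; adj[j, i] <- 1L
        node_sc[j] <- best$new[1]; node_sc[i] <- best$new[2]
      }
    }
    list(adj = adj, score = sum(node_sc))
  }
  best <- climb(matrix(0L, p, p))
  for (r in seq_len(restarts)) {
    set.seed(seed + r)
    ord <- sample.int(p)
    adj0 <- matrix(0L, p, p)
    for (a in seq_len(p - 1)) for (b in (a + 1):p) {
      if (stats::runif(1) < init_prob && sum(adj0[, ord[b]]) < max_parents)
        adj0[ord[a], ord[b]] <- 1L
    }
    cand <- climb(adj0)
    if (cand$score > best$score + 1e-8) best <- cand
  }
  best
}

bn_cpt <- function(codes, nlev, node, parents, n, alpha) {
  r <- nlev[[node]]
  if (length(parents) == 0L) {
    cnt <- tabulate(codes[[node]], r) + alpha
    return(list(tab = cnt / sum(cnt), parents = parents, r = r, q = 1L))
  }
  mult <- 1L; pa_code <- integer(n)
  for (p in parents) {
    pa_code <- pa_code + (codes[[p]] - 1L) * mult
    mult <- mult * nlev[[p]]
  }
  cnt <- matrix(tabulate(pa_code * r + codes[[node]], r * mult) + alpha,
                nrow = r)
  list(tab = sweep(cnt, 2, colSums(cnt), "/"), parents = parents,
       r = r, q = mult)
}

bn_cpt_lookup <- function(cpt, codes_new, node_value) {
  # vectorized P(node = node_value | parents as observed)
  if (length(cpt$parents) == 0L) return(cpt$tab[node_value])
  mult <- 1L; pa_code <- integer(length(codes_new[[cpt$parents[1]]]))
  for (p in cpt$parents) {
    pa_code <- pa_code + (codes_new[[p]] - 1L) * mult
    mult <- mult * attr(codes_new, "nlev")[[p]]
  }
  cpt$tab[cbind(node_value, pa_code + 1L)]
}

#' Bayesian-network membership model
#'
#' Models the joint distribution of the baseline covariates and the trial
#' membership indicator in the stacked trial + target sample as a discrete
#' Bayesian network: continuous covariates are discretized (quintiles by
#' default), structure is learned by score-based hill-climbing with the
#' BIC over DAGs (seeded random restarts; deterministic tie-breaking), and
#' conditional probability tables are maximum-likelihood estimates with
#' light additive smoothing. Membership probabilities are the exact
#' posterior P(trial | X) from the fitted network. The source indicator is
#' forced to stay connected: if the search leaves it isolated, the single
#' best-scoring edge involving it is added.
#'
#' @param trial,target `cohort_table`s.
#' @param covariates covariate names entering the network.
#' @param bins number of discretization bins for continuous covariates.
#' @param max_parents per-node parent limit in the search.
#' @param restarts number of seeded random restarts.
#' @param seed integer seed controlling the restarts.
#' @param alpha additive smoothing pseudo-count for the CPTs.
#' @return `membership_model` with `method = "BN"`, `edges` (data.frame
#'   `from`,`to`), `discretization` map, `cpts`, and `p_trial`.
#' @export
fit_membership_bn <- function(trial, target,
                              covariates = schema_names(cohort_schema(trial)),
                              bins = 5, max_parents = 3, restarts = 5,
                              seed = 1L, alpha = 0.5) {
  schema <- cohort_schema(trial)
  stacked <- rbind(
    data.frame(.source = 1L, as.data.frame(trial)[, covariates, drop = FALSE]),
    data.frame(.source = 0L, as.data.frame(target)[, covariates, drop = FALSE]))
  single <- vapply(covariates, function(nm)
    length(unique(stacked[[nm]])) < 2, TRUE)
  if (any(single)) {
    warning("dropping covariate(s) with a single observed level: ",
            paste(covariates[single], collapse = ", "))
    covariates <- covariates[!single]
  }
  disc <- bn_discretize(stacked, schema, covariates, bins)
  codes <- disc$codes
  codes[[".source"]] <- stacked$.source + 1L
  nlev <- lapply(disc$map, `[[`, "levels")
  nlev[[".source"]] <- 2L
  nodes <- c(".source", covariates)
  n <- nrow(stacked)
  cache <- new.env(parent = emptyenv())
  res <- bn_hill_climb(codes, nlev, nodes, n, max_parents, seed,
                       restarts, init_prob = 0.15, cache = cache)
  adj <- res$adj
  si <- 1L  # index of .source in nodes
  if (sum(adj[si, ]) + sum(adj[, si]) == 0L) {
    # forced connectivity: best single edge touching the source node
    base_sc <- vapply(seq_along(nodes), function(j)
      bn_family_score(codes, nlev, nodes[j], nodes[adj[, j] == 1L], n, cache), 0)
    best <- list(delta = -Inf, move = NULL)
    for (j in seq_along(nodes)[-si]) {
      if (sum(adj[, j]) < max_parents) {
        d <- bn_family_score(codes, nlev, nodes[j],
                             nodes[c(which(adj[, j] == 1L), si)], n, cache) -
          base_sc[j]
        if (d > best$delta) best <- list(delta = d, move = c(j, "in"))
      }
      d <- bn_family_score(codes, nlev, nodes[si],
                           nodes[c(which(adj[, si] == 1L), j)], n, cache) -
        base_sc[si]
      if (d > best$delta) best <- list(delta = d, move = c(j, "out"))
    }
    j <- as.integer(best$move[1])
    if (best$move[2] == "in") adj[si, j] <- 1L else adj[j, si] <- 1L
  }
  cpts <- lapply(seq_along(nodes), function(j)
    bn_cpt(codes, nlev, nodes[j], nodes[adj[, j] == 1L], n, alpha))
  names(cpts) <- nodes
  edges <- which(adj == 1L, arr.ind = TRUE)
  edges <- data.frame(from = nodes[edges[, 1]], to = nodes[edges[, 2]],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  model <- structure(
    list(method = "BN", edges = edges, discretization = disc$map,
         cpts = cpts, nodes = nodes, nlev = nlev, covariates = covariates,
         trial_fraction = mean(stacked$.source), score = res$score),
    class = "membership_model")
  p_trial <- predict_membership_bn(model, trial)
  names(p_trial) <- trial$subject_id
  model$p_trial <- p_trial
  model
}

#' Posterior trial-membership probability from a fitted network
#'
#' With every covariate observed, P(source | X) depends only on the source
#' node's own CPT and the CPTs of its children, evaluated at both source
#' values and normalized.
#'
#' @param model a BN `membership_model`.
#' @param cohort `cohort_table` with the model covariates.
#' @return numeric vector of P(trial | X) per row.
#' @export
predict_membership_bn <- function(model, cohort) {
  n <- nrow(cohort)
  codes_new <- list()
  for (nm in model$covariates) {
    mp <- model$discretization[[nm]]
    codes_new[[nm]] <- if (mp$kind == "binary") as.integer(cohort[[nm]]) + 1L
      else as.integer(cut(cohort[[nm]], mp$breaks, labels = FALSE))
  }
  log_odds <- rep(0, n)
  for (s in c(1L, 2L)) {  # 1 = target, 2 = trial
    cn <- codes_new
    cn[[".source"]] <- rep(s, n)
    attr(cn, "nlev") <- model$nlev
    lp <- log(bn_cpt_lookup(model$cpts[[".source"]], cn, rep(s, n)))
    for (nd in model$nodes[-1]) {
      cpt <- model$cpts[[nd]]
      if (".source" %in% cpt$parents)
        lp <- lp + log(bn_cpt_lookup(cpt, cn, cn[[nd]]))
    }
    log_odds <- log_odds + if (s == 2L) lp else -lp
  }
  stats::plogis(log_odds)
}
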