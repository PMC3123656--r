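# Internal parameter template: maps the free parameter vector to per-group
# model matrices, realizing cross-group equality constraints by shared
# parameter ids. Both degrees-of-freedom bookkeeping and the estimator are
# driven by the same template, so the df arithmetic and the fitted model can
# never disagree.

ordered_items <- function(spec) {
  assigned <- unlist(spec$loadings, use.names = FALSE)
  spec$battery$item_names[spec$battery$item_names %in% assigned]
}

# profile-level shorthand: 0 configural, 1 metric, 2 scalar, 3 uniqueness
build_template <- function(spec, group_names, profile,
                           identification = c("marker", "variance")) {
  stopifnot(inherits(spec, "mgcfa_spec"), inherits(profile, "mgcfa_profile"))
  identification <- match.arg(identification)
  items <- ordered_items(spec)
  p <- length(items)
  factors <- spec$factors
  m <- length(factors)
  G <- length(group_names)
  lvl <- profile$lvl

  if (identification == "variance") {
    if (lvl > 0L)
      stop("variance identification is only available without cross-group ",
           "equality constraints (configural level)", call. = FALSE)
    if (spec$second_order)
      stop("variance identification is not available with a second-order ",
           "factor", call. = FALSE)
  }

  # item -> factor index, marker flags
  fac_of <- integer(p); names(fac_of) <- items
  for (j in seq_len(m)) fac_of[spec$loadings[[factors[j]]]] <- j
  marker <- items %in% unlist(spec$markers)

  ex <- profile$exemptions
  if (nrow(ex)) {
    bad <- setdiff(ex$item, items)
    if (length(bad))
      stop("exempted items not in model: ", paste(bad, collapse = ", "),
           call. = FALSE)
    anchor_hit <- ex$item[ex$class == "loading" & ex$item %in% items[marker]]
    if (length(anchor_hit))
      stop("marker-item loadings are fixed to 1 and cannot be released: ",
           paste(unique(anchor_hit), collapse = ", "), call. = FALSE)
    # with free factor means, each factor needs >= 1 equated intercept
    if (lvl >= 2L && profile$free_factor_means && G > 1L) {
      ex_int <- ex$item[ex$class == "intercept"]
      for (j in seq_len(m)) {
        f_items <- spec$loadings[[factors[j]]]
        if (all(f_items %in% ex_int))
          stop("all intercepts of factor '", factors[j], "' released: ",
               "latent mean comparison is unidentified", call. = FALSE)
      }
    }
  }

  ref_group <- profile$reference_group
  if (is.null(ref_group)) ref_group <- group_names[1L]
  if (!ref_group %in% group_names)
    stop("reference group '", ref_group, "' not among groups: ",
         paste(group_names, collapse = ", "), call. = FALSE)

  # id registry
  ids <- new.env(parent = emptyenv())
  reg <- list(class = character(), item = character(), group = character(),
              log = logical())
  n_id <- 0L
  get_id <- function(key, class, item, group, log) {
    if (!is.null(ids[[key]])) return(ids[[key]])
    n_id <<- n_id + 1L
    ids[[key]] <- n_id
    reg$class[n_id] <<- class; reg$item[n_id] <<- item
    reg$group[n_id] <<- group; reg$log[n_id] <<- log
    n_id
  }

  groups <- vector("list", G); names(groups) <- group_names
  for (g in seq_len(G)) {
    gn <- group_names[g]
    # loadings
    free_load <- if (identification == "marker") which(!marker) else seq_len(p)
    lam_par <- integer(length(free_load))
    for (k in seq_along(free_load)) {
      i <- free_load[k]
      shared <- lvl >= 1L && !is_exempt(profile, "loading", items[i])
      lam_par[k] <- get_id(
        paste0("lam.", items[i], if (!shared) paste0(".", gn)),
        "loading", items[i], if (shared) "*" else gn, FALSE)
    }
    lam_pos <- free_load + (fac_of[free_load] - 1L) * p  # linear index p x m
    mark_idx <- which(marker)
    lam_fix_pos <- if (identification == "marker")
      mark_idx + (fac_of[mark_idx] - 1L) * p else integer()

    # intercepts
    nu_par <- NULL
    if (spec$mean_structure) {
      nu_par <- integer(p)
      for (i in seq_len(p)) {
        shared <- lvl >= 2L && !is_exempt(profile, "intercept", items[i])
        nu_par[i] <- get_id(
          paste0("nu.", items[i], if (!shared) paste0(".", gn)),
          "intercept", items[i], if (shared) "*" else gn, FALSE)
      }
    }

    # uniquenesses (log scale)
    th_par <- integer(p)
    for (i in seq_len(p)) {
      shared <- lvl >= 3L && !is_exempt(profile, "uniqueness", items[i])
      th_par[i] <- get_id(
        paste0("th.", items[i], if (!shared) paste0(".", gn)),
        "uniqueness", items[i], if (shared) "*" else gn, TRUE)
    }

    # factor covariance structure (always group-specific)
    if (spec$second_order) {
      gam_par <- integer(m); d_par <- integer(m)
      for (j in seq_len(m)) {
        gam_par[j] <- get_id(paste0("gam.", factors[j], ".", gn),
                             "gamma", factors[j], gn, FALSE)
        d_par[j] <- get_id(paste0("d.", factors[j], ".", gn),
                           "disturbance", factors[j], gn, TRUE)
      }
      phi <- list(gam_par = gam_par, d_par = d_par)
    } else {
      idx <- which(lower.tri(diag(m), diag = TRUE), arr.ind = TRUE)
      if (identification == "variance")
        idx <- idx[idx[, 1] != idx[, 2], , drop = FALSE]
      phi_par <- integer(nrow(idx))
      for (k in seq_len(nrow(idx))) {
        jj <- idx[k, 2]; kk <- idx[k, 1]  # col <= row
        diag_el <- jj == kk
        phi_par[k] <- get_id(
          paste0("phi.", factors[jj], ".", factors[kk], ".", gn),
          "phi", paste(factors[jj], factors[kk], sep = ":"), gn, diag_el)
      }
      phi <- list(phi_row = idx[, 1], phi_col = idx[, 2], phi_par = phi_par)
    }

    # factor means: reference fixed to 0; others free at scalar and above
    kap_par <- rep(NA_integer_, m)
    if (spec$mean_structure && gn != ref_group && profile$free_factor_means) {
      for (j in seq_len(m))
        kap_par[j] <- get_id(paste0("kap.", factors[j], ".", gn),
                             "kappa", factors[j], gn, FALSE)
    }

    groups[[g]] <- c(list(lam_par = lam_par, lam_pos = lam_pos,
                          lam_fix_pos = lam_fix_pos, nu_par = nu_par,
                          th_par = th_par, kap_par = kap_par), phi)
  }

  par <- data.frame(id = seq_len(n_id), class = reg$class, item = reg$item,
                    group = reg$group, log = reg$log,
                    stringsAsFactors = FALSE)
  par$label <- paste0(substr(par$class, 1, 3), ".", par$item,
                      ifelse(par$group == "*", "", paste0(".", par$group)))
  list(q = n_id, par = par, p = p, m = m, items = items, factors = factors,
       fac_of = fac_of, marker = marker, groups = groups,
       group_names = group_names, reference_group = ref_group,
       second_order = spec$second_order,
       mean_structure = spec$mean_structure,
       identification = identification, profile = profile, spec = spec)
}

# materialize per-group model matrices from the untransformed value vector
template_matrices <- function(tpl, values, group) {
  gt <- tpl$groups[[group]]
  p <- tpl$p; m <- tpl$m
  Lambda <- matrix(0, p, m, dimnames = list(tpl$items, tpl$factors))
  Lambda[gt$lam_fix_pos] <- 1
  Lambda[gt$lam_pos] <- values[gt$lam_par]
  Theta <- values[gt$th_par]; names(Theta) <- tpl$items
  if (tpl$second_order) {
    Gamma <- values[gt$gam_par]; D <- values[gt$d_par]
    Phi <- tcrossprod(Gamma) + diag(D, m)
    phi_extra <- list(Gamma = Gamma, phi2 = 1, D = D)
  } else {
    Phi <- diag(1, m)
    Phi[cbind(gt$phi_row, gt$phi_col)] <- values[gt$phi_par]
    Phi[cbind(gt$phi_col, gt$phi_row)] <- values[gt$phi_par]
    phi_extra <- NULL
  }
  dimnames(Phi) <- list(tpl$factors, tpl$factors)
  nu <- kappa <- NULL
  if (tpl$mean_structure) {
    nu <- values[gt$nu_par]; names(nu) <- tpl$items
    kappa <- numeric(m); names(kappa) <- tpl$factors
    free_k <- !is.na(gt$kap_par)
    kappa[free_k] <- values[gt$kap_par[free_k]]
  }
  c(list(Lambda = Lambda, nu = nu, Theta = Theta, Phi = Phi, kappa = kappa),
    phi_extra)
}
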