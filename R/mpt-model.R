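#' Binary multinomial processing tree (MPT) models
#'
#' An MPT model is a set of processing trees, one per item type, whose
#' branches are products of latent process probabilities \eqn{\theta_s} or
#' their complements \eqn{1-\theta_s}.  Each branch terminates in an
#' observable response category; the probability of a category is the sum of
#' its branch probabilities.  Equality and constant restrictions on the
#' parameters define the identifiable submodels that are actually fitted.
#'
#' @param trees list of trees created by [mpt_tree()].
#' @param parameters optional character vector fixing the parameter order;
#'   defaults to order of first appearance across branches.
#' @param restrictions list of restrictions created by [restr_equal()] /
#'   [restr_fix()].
#' @return an object of class `mpt_model`.
#' @seealso [two_source_model()], [three_source_model()], [read_mpt_model()]
#' @export
mpt_model <- function(trees, parameters = NULL, restrictions = list()) {
  stopifnot(is.list(trees), length(trees) > 0)
  names(trees) <- vapply(trees, function(t) t$item_type, character(1))
  if (anyDuplicated(names(trees)))
    stop("duplicate tree item_type labels")
  seen <- character(0)
  for (tr in trees) {
    for (br in tr$branches) {
      if (!(br$terminal %in% tr$response_categories))
        stop("branch terminal '", br$terminal, "' not in response categories of tree '",
             tr$item_type, "'")
      seen <- c(seen, br$params)
    }
  }
  pars <- unique(seen)
  if (!is.null(parameters)) {
    if (!setequal(parameters, pars))
      stop("'parameters' must name exactly the parameters used in the branches")
    pars <- parameters
  }
  m <- structure(
    list(trees = trees, parameters = pars, restrictions = list()),
    class = "mpt_model"
  )
  if (length(restrictions)) m <- apply_restrictions(m, restrictions)
  m
}

#' Construct one processing tree
#'
#' @param item_type label for the item class the tree models (e.g.
#'   `"ad.high"` for advertisement items of high a priori credibility).
#' @param branches list of branches from [mpt_branch()].
#' @param response_categories ordered character vector of response labels;
#'   defaults to order of first appearance among branch terminals.
#' @export
mpt_tree <- function(item_type, branches, response_categories = NULL) {
  stopifnot(is.character(item_type), length(item_type) == 1L, length(branches) > 0)
  if (is.null(response_categories))
    response_categories <- unique(vapply(branches, function(b) b$terminal, character(1)))
  list(item_type = item_type, branches = branches,
       response_categories = response_categories)
}

#' Construct one tree branch
#'
#' @param terminal response-category label the branch ends in.
#' @param params character vector of parameter names along the branch.
#' @param comp logical vector, `TRUE` where the complement \eqn{1-\theta} of
#'   the corresponding parameter enters the product.
#' @export
mpt_branch <- function(terminal, params = character(0), comp = logical(length(params))) {
  stopifnot(length(params) == length(comp))
  list(terminal = terminal, params = as.character(params), comp = as.logical(comp))
}

#' @export
print.mpt_model <- function(x, ...) {
  res <- resolve_restrictions(x)
  cat("MPT model: ", length(x$trees), " trees, ",
      length(x$parameters), " parameters (", length(res$free), " free), df = ",
      degrees_of_freedom(x), "\n", sep = "")
  cat("Trees: ", paste(names(x$trees), collapse = ", "), "\n", sep = "")
  if (length(x$restrictions)) {
    cat("Restrictions:\n")
    for (r in x$restrictions) {
      if (r$kind == "equal")
        cat("  ", paste(r$params, collapse = " = "), "\n", sep = "")
      else
        cat("  ", r$param, " = ", r$value, "\n", sep = "")
    }
  }
  invisible(x)
}

# ---- restrictions ----------------------------------------------------------

#' Parameter restrictions
#'
#' `restr_equal()` constrains two or more parameters to a common value;
#' `restr_fix()` pins a parameter to a constant in \[0, 1\].  Restrictions are
#' attached to a model with [apply_restrictions()], which collapses the free
#' parameter list into equality classes and recomputes the degrees of
#' freedom.
#'
#' @param ... parameter names (two or more) to be equated.
#' @return an object of class `mpt_restriction`.
#' @export
restr_equal <- function(...) {
  params <- as.character(unlist(list(...)))
  if (length(params) < 2) stop("an equality restriction needs at least two parameters")
  structure(list(kind = "equal", params = params), class = "mpt_restriction")
}

#' @rdname restr_equal
#' @param param parameter name.
#' @param value constant in \[0, 1\].
#' @export
restr_fix <- function(param, value) {
  stopifnot(is.numeric(value), length(value) == 1L)
  if (value < 0 || value > 1) stop("constant restriction outside [0, 1]: ", value)
  structure(list(kind = "fix", param = as.character(param), value = value),
            class = "mpt_restriction")
}

#' Attach restrictions to a model
#'
#' Restrictions accumulate: the returned model carries the union of the
#' existing and the new restriction set.  The combined set is checked for
#' conflicts (a parameter forced to two distinct constants) and for unknown
#' parameter names.  Applying the same set twice is a no-op.
#'
#' @param model an [mpt_model()].
#' @param restrictions a single restriction or a list of restrictions.
#' @return the model with the enlarged restriction set.
#' @export
apply_restrictions <- function(model, restrictions) {
  stopifnot(inherits(model, "mpt_model"))
  if (inherits(restrictions, "mpt_restriction")) restrictions <- list(restrictions)
  for (r in restrictions) {
    if (!inherits(r, "mpt_restriction")) stop("not an mpt_restriction object")
    ref <- if (r$kind == "equal") r$params else r$param
    unknown <- setdiff(ref, model$parameters)
    if (length(unknown))
      stop("restriction references unknown parameter(s): ",
           paste(unknown, collapse = ", "))
  }
  model$restrictions <- c(model$restrictions, restrictions)
  # validate (errors on conflict) and drop duplicates made redundant
  resolve_restrictions(model)
  model
}

#' Resolve a model's restriction set into equality classes
#'
#' Internal workhorse shared by the probability, fitting and df code.
#' Returns the free parameters (one representative per equality class, in
#' model parameter order), an index `map` from every model parameter into the
#' free vector (`NA` for parameters fixed to a constant), and the named
#' vector of fixed values.
#'
#' @param model an [mpt_model()].
#' @return list with elements `free`, `map`, `fixed`.
#' @keywords internal
#' @export
resolve_restrictions <- function(model) {
  pars <- model$parameters
  np <- length(pars)
  parent <- seq_len(np)                      # union-find over parameter indices
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    parent
  }
  for (r in model$restrictions) {
    if (r$kind != "equal") next
    idx <- match(r$params, pars)
    for (j in idx[-1]) parent <- union_(idx[1], j)
  }
  root <- vapply(seq_len(np), find, integer(1))
  # propagate constants to whole classes, detect conflicts
  fixed_val <- rep(NA_real_, np)             # per class root
  for (r in model$restrictions) {
    if (r$kind != "fix") next
    cl <- root[match(r$param, pars)]
    if (!is.na(fixed_val[cl]) && abs(fixed_val[cl] - r$value) > 1e-12)
      stop("restriction conflict: parameter class of '", r$param,
           "' forced to both ", fixed_val[cl], " and ", r$value)
    fixed_val[cl] <- r$value
  }
  free_roots <- sort(unique(root[is.na(fixed_val[root])]))
  free <- pars[free_roots]
  map <- match(root, free_roots)             # NA where class is fixed
  fixed <- fixed_val[root]
  names(fixed) <- pars
  list(free = free, map = map, fixed = fixed)
}

#' Free parameters of a restricted model
#' @param model an [mpt_model()].
#' @return character vector, one representative name per equality class.
#' @export
free_parameters <- function(model) resolve_restrictions(model)$free

#' Expand free-parameter values to the full parameter vector
#'
#' @param model an [mpt_model()].
#' @param theta named numeric vector covering every free parameter (extra
#'   names are ignored).
#' @return named numeric vector over all model parameters, with equality
#'   classes filled from their representative and constants substituted.
#' @export
expand_theta <- function(model, theta) {
  res <- resolve_restrictions(model)
  missing <- setdiff(res$free, names(theta))
  if (length(missing))
    stop("missing value for parameter(s): ", paste(missing, collapse = ", "))
  th <- theta[res$free]
  if (any(!is.finite(th)) || any(th < 0) || any(th > 1))
    stop("parameter values must lie in [0, 1]")
  full <- ifelse(is.na(res$map), res$fixed, th[res$map])
  names(full) <- model$parameters
  full
}

# ---- probabilities ---------------------------------------------------------

#' Category probabilities of an MPT model
#'
#' Computes, for every tree, the probability of each response category at the
#' supplied parameter values.  Restricted parameters are resolved first, so
#' `theta` needs to cover only the free parameters.  Branch products are
#' evaluated exactly, so boundary values 0 and 1 are allowed.
#'
#' @param model an [mpt_model()].
#' @param theta named numeric vector of free-parameter values in \[0, 1\].
#' @return named list, one named probability vector per tree; each vector is
#'   nonnegative and sums to 1.
#' @export
category_probabilities <- function(model, theta) {
  full <- expand_theta(model, theta)
  out <- lapply(model$trees, function(tr) {
    p <- stats::setNames(numeric(length(tr$response_categories)),
                         tr$response_categories)
    for (br in tr$branches) {
      v <- full[br$params]
      v[br$comp] <- 1 - v[br$comp]
      p[br$terminal] <- p[br$terminal] + prod(v)
    }
    p
  })
  out
}

#' Degrees of freedom of a (restricted) MPT model
#'
#' Free response categories, \eqn{\sum_{trees}(K_t - 1)}, minus the number of
#' free parameters after restriction resolution.  A negative value flags an
#' over-parameterised (non-identifiable) model.
#'
#' @param model an [mpt_model()].
#' @return integer, possibly negative.
#' @export
degrees_of_freedom <- function(model) {
  free_cats <- sum(vapply(model$trees,
                          function(tr) length(tr$response_categories) - 1L,
                          integer(1)))
  free_cats - length(free_parameters(model))
}

#' Local identifiability check by Jacobian rank
#'
#' Evaluates the numeric Jacobian of the stacked category probabilities with
#' respect to the free parameters at `theta0` (central differences) and
#' reports its rank from the singular values.  The model is locally
#' identifiable at `theta0` when the rank equals the number of free
#' parameters.
#'
#' @param model an [mpt_model()].
#' @param theta0 named vector of free-parameter values; values on the
#'   boundary are perturbed inward with a warning.
#' @param h finite-difference step.
#' @return list with `rank`, `n_free`, `identifiable`, `singular_values`.
#' @export
check_local_identifiability <- function(model, theta0 = NULL, h = 1e-6) {
  free <- free_parameters(model)
  if (is.null(theta0)) theta0 <- stats::setNames(rep(0.5, length(free)), free)
  th <- theta0[free]
  if (any(is.na(th))) stop("theta0 must cover all free parameters")
  if (any(th <= h) || any(th >= 1 - h)) {
    warning("theta0 on or near the [0,1] boundary; perturbing inward")
    th <- pmin(pmax(th, 2 * h), 1 - 2 * h)
  }
  pvec <- function(t) {
    names(t) <- free
    unlist(category_probabilities(model, t), use.names = FALSE)
  }
  J <- vapply(seq_along(free), function(j) {
    up <- th; up[j] <- up[j] + h
    dn <- th; dn[j] <- dn[j] - h
    (pvec(up) - pvec(dn)) / (2 * h)
  }, numeric(length(pvec(th))))
  sv <- svd(J, nu = 0, nv = 0)$d
  rk <- sum(sv > max(dim(J)) * max(sv, 0) * 1e-10)
  list(rank = rk, n_free = length(free), identifiable = rk == length(free),
       singular_values = sv)
}

# ---- compiled form for fast likelihood evaluation --------------------------

# Structural matrices (branch x parameter exponent counts) in the classic
# product form p_branch = prod theta^A * (1-theta)^B; used by the fitting
# code where theta is guaranteed strictly inside (0,1).
compile_mpt <- function(model) {
  pars <- model$parameters
  np <- length(pars)
  nb <- sum(vapply(model$trees, function(tr) length(tr$branches), integer(1)))
  A <- matrix(0, nb, np, dimnames = list(NULL, pars))
  B <- matrix(0, nb, np, dimnames = list(NULL, pars))
  cat_tree <- character(0); cat_label <- character(0)
  for (tr in model$trees) {
    cat_tree <- c(cat_tree, rep(tr$item_type, length(tr$response_categories)))
    cat_label <- c(cat_label, tr$response_categories)
  }
  cat_key <- paste(cat_tree, cat_label, sep = "\r")
  branch_cat <- integer(nb)
  i <- 0L
  for (tr in model$trees) {
    for (br in tr$branches) {
      i <- i + 1L
      for (k in seq_along(br$params)) {
        j <- match(br$params[k], pars)
        if (br$comp[k]) B[i, j] <- B[i, j] + 1 else A[i, j] <- A[i, j] + 1
      }
      branch_cat[i] <- match(paste(tr$item_type, br$terminal, sep = "\r"), cat_key)
    }
  }
  res <- resolve_restrictions(model)
  list(A = A, B = B, branch_cat = branch_cat, n_cat = length(cat_key),
       cat_tree = cat_tree, cat_label = cat_label,
       free = res$free, map = res$map, fixed = res$fixed)
}

# Category probabilities from a compiled model at full parameter vector theta
# (strictly inside (0,1)); returns vector over stacked categories.
compiled_cat_probs <- function(cm, full) {
  pb <- exp(cm$A %*% log(full) + cm$B %*% log1p(-full))
  as.numeric(rowsum(pb, cm$branch_cat, reorder = TRUE))
}

# ---- model-specification text format ---------------------------------------

#' Read an MPT model from its text specification
#'
#' One line per branch: `tree_label  category_label  expression`, where the
#' expression is a `*`-separated product of parameter names and complements
#' written `(1-name)`.  Lines starting with `#` are comments.  Restrictions
#' may be given in the same file or a companion file as
#' `restrict: p1 = p2 = p3` (equality) and `set: p = 0.5` (constant).
#'
#' @param path file path of the model specification.
#' @param restrictions_path optional companion restriction file.
#' @return an [mpt_model()].
#' @export
read_mpt_model <- function(path, restrictions_path = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (!is.null(restrictions_path))
    lines <- c(lines, readLines(restrictions_path, warn = FALSE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  branches <- list(); tree_order <- character(0)
  restr <- list()
  for (ln in lines) {
    if (grepl("^restrict:", ln)) {
      ps <- trimws(strsplit(sub("^restrict:", "", ln), "=", fixed = TRUE)[[1]])
      restr[[length(restr) + 1L]] <- do.call(restr_equal, as.list(ps))
      next
    }
    if (grepl("^set:", ln)) {
      kv <- trimws(strsplit(sub("^set:", "", ln), "=", fixed = TRUE)[[1]])
      if (length(kv) != 2) stop("malformed set: line: ", ln)
      restr[[length(restr) + 1L]] <- restr_fix(kv[1], as.numeric(kv[2]))
      next
    }
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(tok) < 3) stop("malformed branch line: ", ln)
    tree <- tok[1]; category <- tok[2]
    expr <- paste(tok[-(1:2)], collapse = "")
    facs <- strsplit(expr, "*", fixed = TRUE)[[1]]
    params <- character(0); comp <- logical(0)
    for (f in facs) {
      if (grepl("^\\(1-.+\\)$", f)) {
        params <- c(params, sub("^\\(1-(.+)\\)$", "\\1", f)); comp <- c(comp, TRUE)
      } else if (grepl("^[A-Za-z][A-Za-z0-9_.]*$", f)) {
        params <- c(params, f); comp <- c(comp, FALSE)
      } else stop("cannot parse factor '", f, "' in line: ", ln)
    }
    tree_order <- union(tree_order, tree)
    branches[[length(branches) + 1L]] <-
      list(tree = tree, branch = mpt_branch(category, params, comp))
  }
  trees <- lapply(tree_order, function(tl) {
    brs <- lapply(Filter(function(b) b$tree == tl, branches), `[[`, "branch")
    mpt_tree(tl, brs)
  })
  mpt_model(trees, restrictions = restr)
}

#' Write an MPT model to the text specification format
#'
#' @param model an [mpt_model()].
#' @param path output file path.
#' @param write_restrictions include the model's restriction set in the file.
#' @return `path`, invisibly.
#' @export
write_mpt_model <- function(model, path, write_restrictions = TRUE) {
  out <- character(0)
  for (tr in model$trees) {
    for (br in tr$branches) {
      fac <- ifelse(br$comp, paste0("(1-", br$params, ")"), br$params)
      out <- c(out, sprintf("%-14s %-9s %s", tr$item_type, br$terminal,
                            paste(fac, collapse = " * ")))
    }
  }
  if (write_restrictions) {
    for (r in model$restrictions) {
      out <- c(out, if (r$kind == "equal")
        paste0("restrict: ", paste(r$params, collapse = " = "))
        else paste0("set: ", r$param, " = ", r$value))
    }
  }
  writeLines(out, path)
  invisible(path)
}
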