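## Initial-tissue generation: Poisson-disk points in a disk, Voronoi
## tessellation by half-plane clipping, Lloyd regularisation, then mechanical
## relaxation. The Voronoi step identifies shared mesh vertices exactly by
## the set of objects (generators / disk edges) defining each vertex, so the
## per-cell polygons assemble into a consistent shared-vertex mesh without
## coordinate rounding.

## best-candidate (Mitchell) sampling: approximately Poisson-disk
poisson_disk_points <- function(n, radius, candidates = 12) {
  pts <- matrix(NA_real_, n, 2)
  r <- radius * sqrt(stats::runif(1)); a <- stats::runif(1, 0, 2 * pi)
  pts[1, ] <- c(r * cos(a), r * sin(a))
  for (i in seq_len(n)[-1]) {
    rc <- radius * sqrt(stats::runif(candidates))
    ac <- stats::runif(candidates, 0, 2 * pi)
    cx <- rc * cos(ac); cy <- rc * sin(ac)
    ex <- pts[seq_len(i - 1), 1]; ey <- pts[seq_len(i - 1), 2]
    dmin <- vapply(seq_len(candidates), function(k)
      min((cx[k] - ex)^2 + (cy[k] - ey)^2), 0)
    best <- which.max(dmin)
    pts[i, ] <- c(cx[best], cy[best])
  }
  pts
}

## clip labelled polygon (x, y, lab: m x 2 object ids) by the half plane
## s(v) <= 0 where s = (v - mid) . u ; new vertices get label (shared, obj)
clip_labelled <- function(px, py, lab, s, obj) {
  n <- length(px)
  keep <- s <= 0
  if (all(keep)) return(list(x = px, y = py, lab = lab))
  if (!any(keep)) return(NULL)
  nx <- numeric(0); ny <- numeric(0); nl <- matrix(0L, 0, 2)
  j <- c(seq_len(n)[-1], 1L)
  for (e in seq_len(n)) {
    a <- e; b <- j[e]
    if (keep[a]) {
      nx <- c(nx, px[a]); ny <- c(ny, py[a]); nl <- rbind(nl, lab[a, ])
    }
    if (xor(keep[a], keep[b])) {
      t <- s[a] / (s[a] - s[b])
      shared <- intersect(lab[a, ], lab[b, ])[1]
      nx <- c(nx, px[a] + t * (px[b] - px[a]))
      ny <- c(ny, py[a] + t * (py[b] - py[a]))
      nl <- rbind(nl, c(shared, obj))
    }
  }
  list(x = nx, y = ny, lab = nl)
}

## Voronoi cells of pts clipped to a regular m-gon of the given radius.
## Returns per-cell polygons with globally consistent vertex keys.
voronoi_cells <- function(pts, radius, m = 48) {
  n <- nrow(pts)
  ang <- 2 * pi * (seq_len(m) - 1) / m
  dx <- radius * cos(ang); dy <- radius * sin(ang)
  dlab <- cbind(-c(m, seq_len(m - 1)), -seq_len(m))  # vertex e on edges e-1, e
  out <- vector("list", n)
  for (i in seq_len(n)) {
    px <- dx; py <- dy; lab <- dlab
    d2 <- (pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2
    ord <- order(d2)[-1]
    for (jj in ord) {
      dij <- sqrt(d2[jj])
      maxd <- sqrt(max((px - pts[i, 1])^2 + (py - pts[i, 2])^2))
      if (dij / 2 > maxd) break
      ux <- (pts[jj, 1] - pts[i, 1]) / dij
      uy <- (pts[jj, 2] - pts[i, 2]) / dij
      s <- (px - (pts[i, 1] + pts[jj, 1]) / 2) * ux +
           (py - (pts[i, 2] + pts[jj, 2]) / 2) * uy
      cl <- clip_labelled(px, py, lab, s, jj)
      if (is.null(cl)) stop("voronoi: generator with empty cell")
      px <- cl$x; py <- cl$y; lab <- cl$lab
    }
    ## canonical vertex identity: a Voronoi vertex inside the disk is the
    ## circumcenter of a generator triple {i, j, k}; on the disk rim it is a
    ## bisector/disk-edge crossing {edge, i, j}; disk corners are {e1, e2}
    keys <- vapply(seq_along(px), function(v) {
      l <- lab[v, ]
      gens <- sort(unique(c(i, l[l > 0])))
      edges <- sort(-l[l < 0])
      if (length(edges) == 0)
        paste0("T", paste(gens, collapse = "."))
      else if (length(edges) == 1)
        paste0("D", edges, "_", paste(gens, collapse = "."))
      else paste0("K", paste(edges, collapse = "."))
    }, "")
    dup <- keys == c(keys[-1], keys[1])
    out[[i]] <- list(x = px[!dup], y = py[!dup], key = keys[!dup])
  }
  out
}

voronoi_mesh <- function(pts, radius, lloyd = 3) {
  for (it in seq_len(lloyd)) {
    cells <- voronoi_cells(pts, radius)
    pts <- t(vapply(cells, function(cl)
      poly_centroid(cbind(cl$x, cl$y)), c(0, 0)))
  }
  cells <- voronoi_cells(pts, radius)
  allkeys <- unlist(lapply(cells, `[[`, "key"), use.names = FALSE)
  ux <- unlist(lapply(cells, `[[`, "x"), use.names = FALSE)
  uy <- unlist(lapply(cells, `[[`, "y"), use.names = FALSE)
  ids <- match(allkeys, unique(allkeys))
  nv <- max(ids)
  pos <- cbind(as.vector(rowsum(ux, ids)), as.vector(rowsum(uy, ids))) /
    as.vector(rowsum(rep(1, length(ids)), ids))
  k <- lengths(lapply(cells, `[[`, "key"))
  cyc <- split(ids, rep.int(seq_along(cells), k))
  cyc <- lapply(cyc, function(v) v[c(TRUE, v[-1] != v[-length(v)])])
  cyc <- lapply(cyc, function(v) if (v[1] == v[length(v)] && length(v) > 1)
    v[-length(v)] else v)
  list(pos = pos, cells = unname(cyc))
}

#' Generate an initial tissue
#'
#' Builds a roughly circular confluent tissue of \code{n_cells} polygonal
#' cells: approximately Poisson-disk generator points in a disk, a Voronoi
#' tessellation clipped to the disk, a few Lloyd iterations to regularise cell
#' sizes, rescaling to unit mean cell area, and a short mechanical settling
#' relaxation under \code{config}. The returned tissue has unit mean area (the
#' natural area) and a cell-size coefficient of variation well below 0.1.
#' The settling is deliberately short: full equilibration of the free-boundary
#' tissue squeezes out rim cells, which is exactly the extrusion process the
#' growth dynamics (with its T2 bookkeeping) is responsible for.
#'
#' @param n_cells number of cells (>= 7).
#' @param seed RNG seed; \code{NULL} continues the current RNG stream.
#' @param config a \code{\link{sim_config}} for the state defaults and the
#'   final relaxation.
#' @param lloyd number of Lloyd iterations.
#' @param relax_steps cap on relaxation steps.
#' @return a \code{\link{new_tissue}} object.
#' @export
generate_initial_tissue <- function(n_cells = 250, seed = NULL,
                                    config = sim_config(), lloyd = 15,
                                    relax_steps = 10) {
  stopifnot(n_cells >= 7)
  if (!is.null(seed)) set.seed(seed)
  radius <- sqrt(n_cells / pi)
  pts <- poisson_disk_points(n_cells, radius)
  mesh <- voronoi_mesh(pts, radius, lloyd = lloyd)
  tis <- new_tissue(mesh$pos, mesh$cells, config = config)
  tis$pos <- tis$pos / sqrt(mean(cell_areas(tis)))
  attr(tis, "cache") <- NULL
  tis <- relax(tis, config, force_tol = config$relax_force_tol,
               max_steps = relax_steps, t1_sweeps = TRUE)
  tis$pos <- tis$pos / sqrt(mean(cell_areas(tis)))  # back to unit mean area
  attr(tis, "cache") <- NULL
  tis
}

## ---- plain-text snapshot format -------------------------------------------

#' Read and write tissue snapshots
#'
#' Plain-text, self-describing mesh dialect: a header, a counts line,
#' one line per vertex, one line per cell (vertex count followed by 1-based
#' vertex indices), then a per-cell state table. Round-trips bit-identically.
#'
#' @param tissue a tissue object.
#' @param file path.
#' @return \code{read_tissue} returns a tissue; \code{write_tissue} the file
#'   path, invisibly.
#' @export
write_tissue <- function(tissue, file) {
  con <- file(file, "w")
  on.exit(close(con))
  nv <- nrow(tissue$pos); nc <- length(tissue$cells)
  writeLines(c("mcevertex-tissue 1", paste(nv, nc)), con)
  writeLines(sprintf("%.17g %.17g", tissue$pos[, 1], tissue$pos[, 2]), con)
  writeLines(vapply(tissue$cells, function(v)
    paste(c(length(v), v), collapse = " "), ""), con)
  st <- tissue$state
  writeLines(paste("lam gam trait clock cycle_len natural_area mitotic",
                   "pre_mitotic_area mitotic_elapsed id"), con)
  writeLines(sprintf("%.17g %.17g %s %.17g %.17g %.17g %d %s %.17g %d",
                     st$lam, st$gam,
                     ifelse(is.na(st$trait), "NA", as.character(st$trait)),
                     st$clock, st$cycle_len, st$natural_area,
                     as.integer(st$mitotic),
                     ifelse(is.na(st$pre_mitotic_area), "NA",
                            sprintf("%.17g", st$pre_mitotic_area)),
                     st$mitotic_elapsed, st$id), con)
  invisible(file)
}

#' @rdname write_tissue
#' @export
read_tissue <- function(file) {
  ln <- readLines(file)
  if (!startsWith(ln[1], "mcevertex-tissue"))
    stop("not a mcevertex tissue snapshot: ", file)
  counts <- as.integer(strsplit(ln[2], " ")[[1]])
  nv <- counts[1]; nc <- counts[2]
  pos <- do.call(rbind, lapply(strsplit(ln[3:(2 + nv)], " "), as.numeric))
  cl <- lapply(strsplit(ln[(3 + nv):(2 + nv + nc)], " "), function(s) {
    v <- as.integer(s)
    v[-1]
  })
  hdr <- strsplit(ln[3 + nv + nc], " ")[[1]]
  stl <- strsplit(ln[(4 + nv + nc):(3 + nv + nc + nc)], " ")
  stm <- do.call(rbind, stl)
  st <- list(
    lam = as.numeric(stm[, 1]), gam = as.numeric(stm[, 2]),
    trait = suppressWarnings(as.integer(stm[, 3])),
    clock = as.numeric(stm[, 4]), cycle_len = as.numeric(stm[, 5]),
    natural_area = as.numeric(stm[, 6]), mitotic = stm[, 7] == "1",
    pre_mitotic_area = suppressWarnings(as.numeric(stm[, 8])),
    mitotic_elapsed = as.numeric(stm[, 9]),
    id = as.integer(stm[, 10]))
  stopifnot(identical(hdr[1], "lam"))
  new_tissue(pos, cl, state = st)
}

## ---- run outputs -----------------------------------------------------------

#' Write the complete output set of a growth run
#'
#' Writes the final tissue snapshot, the event log (tab-delimited), the
#' tissue-size series, the fitness series and a JSON run manifest with file
#' checksums into \code{out_dir}.
#'
#' @param run a \code{\link{run_growth}} result.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the manifest as a list.
#' @export
write_outputs <- function(run, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  fsnap <- file.path(out_dir, "final_tissue.txt")
  write_tissue(run$tissue, fsnap)
  fev <- file.path(out_dir, "events.tsv")
  utils::write.table(run$events, fev, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  fsz <- file.path(out_dir, "size_series.tsv")
  utils::write.table(data.frame(time = run$times, cells = run$g),
                     fsz, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(fsnap, fev, fsz)
  fit <- tryCatch(fitness_series(run), error = function(e) NULL)
  if (!is.null(fit)) {
    ffit <- file.path(out_dir, "fitness_series.tsv")
    utils::write.table(fit, ffit, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, ffit)
  }
  manifest <- list(
    package = "mcevertex",
    version = as.character(utils::packageVersion("mcevertex")),
    seed = run$config$seed,
    start_cells = run$g[1], end_cells = run$g[length(run$g)],
    n_divisions = sum(run$events$kind == "division"),
    n_eliminations = sum(run$events$kind == "t2"),
    n_t1 = sum(run$events$kind == "t1"),
    config = unclass(run$config[!vapply(run$config, is.list, TRUE)]),
    files = lapply(files, function(f)
      list(name = basename(f), md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' One-parameter sweep of growth simulations
#'
#' Runs \code{\link{run_growth}} for every value of one mechanical/growth
#' parameter (optionally replicated with derived seeds) and aggregates the
#' temporal-mean elimination rate, fitness, and heterogeneity summaries — the
#' input of \code{\link{fit_gaussian_response}}.
#'
#' @param config template \code{\link{sim_config}}.
#' @param param one of \code{"lam0"}, \code{"gam0"}, \code{"theta_T1"},
#'   \code{"kappa"}, \code{"mu"}.
#' @param values parameter values to sweep.
#' @param replicates runs per value.
#' @param n_target cell count at which each run stops.
#' @param t_end optional time cap per run, so that parameter values with
#'   near-total elimination (stalled growth) still terminate.
#' @return data frame with one row per run: parameter value, replicate,
#'   temporal-mean elimination rate, fitness, size CV, stress-magnitude
#'   variance, event counts and final time. Failed runs are kept as rows of
#'   \code{NA}.
#' @export
sweep_parameter <- function(config, param, values, replicates = 1,
                            n_target = 1000, t_end = NULL) {
  stopifnot(param %in% c("lam0", "gam0", "theta_T1", "kappa", "mu"))
  if (length(values) == 0)
    return(data.frame(value = numeric(0), replicate = integer(0),
                      eps_mean = numeric(0), phi = numeric(0),
                      cv_size = numeric(0), var_stress = numeric(0),
                      n_div = integer(0), n_elim = integer(0),
                      t_final = numeric(0)))
  rows <- list()
  for (vi in seq_along(values)) {
    for (rep_i in seq_len(replicates)) {
      cfg <- config
      cfg[[param]] <- values[vi]
      if (param == "mu") cfg$cycle_len_mean <- log(2) / values[vi]
      cfg$seed <- as.integer((config$seed + 7877L * vi + 131L * rep_i) %%
                               .Machine$integer.max)
      res <- tryCatch({
        run <- run_growth(cfg, n_target = n_target, t_end = t_end)
        er <- elimination_rate(run, window_cells = 50, burn_in = 100)
        data.frame(value = values[vi], replicate = rep_i,
                   eps_mean = er$mean,
                   phi = tryCatch(mean(tissue_fitness(run)$phi, na.rm = TRUE),
                                  error = function(e) NA_real_),
                   cv_size = mean(run$stats$cv_size, na.rm = TRUE),
                   var_stress = mean(run$stats$var_stress, na.rm = TRUE),
                   n_div = sum(run$events$kind == "division"),
                   n_elim = sum(run$events$kind == "t2"),
                   t_final = max(run$times))
      }, error = function(e) {
        warning(sprintf("sweep run failed at %s = %g (rep %d): %s",
                        param, values[vi], rep_i, conditionMessage(e)))
        data.frame(value = values[vi], replicate = rep_i, eps_mean = NA,
                   phi = NA, cv_size = NA, var_stress = NA,
                   n_div = NA, n_elim = NA, t_final = NA)
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  do.call(rbind, rows)
}
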