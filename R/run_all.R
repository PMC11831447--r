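#' Run the full pipeline from a flat key=value config file
#'
#' One-command end-to-end run: simulate (or load) a dataset, score, tier,
#' partition regions, layer niches, compute co-localization and the
#' neighbourhood correlation, and write every stage result as a headered
#' TSV plus a JSON run manifest. All randomness flows from the single
#' `seed` key.
#'
#' Config keys: `mode` (`synthetic`, the default, or `real`); in real mode
#' `counts_dir`, `positions`, `signatures` (paths); in synthetic mode any
#' [sim_config()] field (e.g. `grid_rows=60`, `coupling_rho=0.6`). Analysis
#' keys: `min_z`, `min_niche_size`, `layer_mode`, `k`, `B`, `seed`.
#'
#' @param config_path path to the key=value config file.
#' @param out_dir output directory (created if needed).
#' @return The run manifest (list), invisibly. On stage failure the
#'   manifest records the failed stage, partial outputs are retained, and
#'   the error is re-thrown.
#' @export
run_all <- function(config_path, out_dir) {
  if (!file.exists(config_path)) stop("config file not found: ", config_path)
  cfg <- read_flat_config(config_path)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", out_dir)
  }
  mode <- cfg_get(cfg, "mode", "synthetic")
  seed <- as.integer(cfg_get(cfg, "seed", 0))

  manifest <- list(
    config_path = normalizePath(config_path),
    config_md5 = unname(tools::md5sum(config_path)),
    seed = seed,
    package_version = as.character(utils::packageVersion("hexniche")),
    mode = mode, stages = list())
  stage_t0 <- NULL
  failed <- NULL
  record <- function(name, paths) {
    manifest$stages[[name]] <<- list(
      outputs = as.list(paths),
      wall_time_s = round(as.numeric(Sys.time()) - stage_t0, 3))
  }
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  result <- tryCatch({
    # --- stage: input -----------------------------------------------------
    stage_t0 <- as.numeric(Sys.time())
    if (mode == "synthetic") {
      sim_keys <- intersect(names(cfg), names(formals(sim_config)))
      args <- lapply(cfg[sim_keys], utils::type.convert, as.is = TRUE)
      args$seed <- seed
      sim <- simulate_visium(do.call(sim_config, args))
      counts <- sim$counts; spots <- sim$spots; sigs <- sim$signatures
      data_dir <- file.path(out_dir, "data")
      write_visium(counts, spots, data_dir)
      write_signatures(sigs, file.path(data_dir, "signatures.tsv"))
      utils::write.table(sim$truth, file.path(out_dir, "truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      record("input", c(data_dir, file.path(out_dir, "truth.tsv")))
    } else if (mode == "real") {
      for (key in c("counts_dir", "positions", "signatures")) {
        if (is.null(cfg[[key]])) stop("real mode requires config key: ", key)
        probe <- cfg[[key]]
        if (!file.exists(probe)) stop("input path not found: ", probe)
      }
      vis <- read_visium(cfg$counts_dir, cfg$positions)
      counts <- vis$counts; spots <- vis$spots
      sigs <- read_signatures(cfg$signatures)
      record("input", c(cfg$counts_dir, cfg$positions, cfg$signatures))
    } else {
      stop("unknown mode: ", mode)
    }

    # --- stage: analysis --------------------------------------------------
    stage_t0 <- as.numeric(Sys.time())
    fit <- leading_edge(
      counts, spots, sigs,
      min_z = as.numeric(cfg_get(cfg, "min_z", 0)),
      min_niche_size = as.integer(cfg_get(cfg, "min_niche_size", 10)),
      layer_mode = cfg_get(cfg, "layer_mode", "hull_peel"),
      k = as.integer(cfg_get(cfg, "k", 1)),
      B = as.integer(cfg_get(cfg, "B", 1000)),
      seed = seed)
    record("analysis", character(0))

    # --- stage: outputs ---------------------------------------------------
    stage_t0 <- as.numeric(Sys.time())
    paths <- write_leading_edge_tables(fit, out_dir)
    record("outputs", paths)
    fit
  }, error = function(e) {
    failed <<- conditionMessage(e)
    e
  })
  if (!is.null(failed)) {
    manifest$failed_stage <- failed
    write_manifest()
    stop(result)
  }
  write_manifest()
  invisible(manifest)
}

read_flat_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  stats::setNames(lapply(kv, function(x) trimws(x[2])),
                  vapply(kv, function(x) trimws(x[1]), character(1)))
}

cfg_get <- function(cfg, key, default) {
  if (is.null(cfg[[key]])) default else cfg[[key]]
}

## stage result tables, all keyed by spot_id
write_leading_edge_tables <- function(fit, out_dir) {
  tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  ids <- fit$spots$spot_id
  paths <- character(0)

  sc <- data.frame(spot_id = ids,
                   lapply(fit$scores, function(s) as.numeric(s[ids])))
  paths <- c(paths, tsv(sc, "scores.tsv"))
  ti <- data.frame(spot_id = ids,
                   lapply(fit$tiers, function(t) as.integer(t$tiers[ids])))
  paths <- c(paths, tsv(ti, "tiers.tsv"))
  paths <- c(paths, tsv(data.frame(spot_id = ids,
                                   region = as.character(fit$regions[ids])),
                        "regions.tsv"))

  if (length(fit$layerings)) {
    lt <- do.call(rbind, lapply(seq_along(fit$layerings), function(i) {
      data.frame(niche_id = i, spot_id = names(fit$layerings[[i]]$layer),
                 layer = as.integer(fit$layerings[[i]]$layer))
    }))
    pr <- do.call(rbind, lapply(seq_along(fit$profiles), function(i) {
      p <- fit$profiles[[i]]
      cbind(niche_id = i, p$profile,
            trend_rho = p$trend$rho, trend_p = p$trend$p_value)
    }))
  } else {
    lt <- data.frame(niche_id = integer(0), spot_id = character(0),
                     layer = integer(0))
    pr <- data.frame(niche_id = integer(0), layer = integer(0),
                     n_spots = integer(0), mean_score = numeric(0),
                     trend_rho = numeric(0), trend_p = numeric(0))
  }
  paths <- c(paths, tsv(lt, "layers.tsv"), tsv(pr, "layer_profiles.tsv"))

  paths <- c(paths, tsv(data.frame(spot_id = names(fit$tricoloc$product),
                                   product = as.integer(fit$tricoloc$product)),
                        "coloc.tsv"))
  if (!is.null(fit$neighborhood)) {
    nb <- fit$neighborhood$table
    nb$rho <- fit$neighborhood$rho
    nb$p_perm <- fit$neighborhood$p_perm
    paths <- c(paths, tsv(nb, "neighborhood.tsv"))
  }
  paths
}
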