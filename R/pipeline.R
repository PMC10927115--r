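#' Ablation configurations
#'
#' Maps the named ablation modes onto configuration switches:
#' \describe{
#'   \item{full}{the complete objective (KL + high-confidence CE +
#'     orthogonal and diagonal continuity, tied and corner-masked
#'     kernels).}
#'   \item{ce+ortho}{no KL term, q_cut = 0 (all spots in the cross
#'     entropy), no diagonal continuity.}
#'   \item{ce+ortho+diag}{no KL term, q_cut = 0, diagonal continuity
#'     restored.}
#'   \item{hce+ortho+diag}{no KL term, q_cut = 0.5.}
#'   \item{KL+hce+ortho}{full objective without the diagonal continuity
#'     term.}
#'   \item{no_distance}{distance ties disabled (every active tap has its
#'     own weight); corners still masked.}
#'   \item{no_distance+corners}{ties disabled and corner masking disabled.}
#' }
#'
#' @param mode one of the names above.
#' @param platform `"visium"` or `"stereo"`.
#' @param n cluster number.
#' @return a \code{\link{trainConfig}} list with the switches applied.
#' @export
ablationConfig <- function(mode = c("full", "ce+ortho", "ce+ortho+diag",
                                    "hce+ortho+diag", "KL+hce+ortho",
                                    "no_distance", "no_distance+corners"),
                           platform = "visium", n) {
  mode <- match.arg(mode)
  cfg <- trainConfig(platform, n)
  dg <- cfg$cont_weights[["diag"]]
  switch(mode,
    "ce+ortho" = {
      cfg$loss_weights[["kl"]] <- 0
      cfg$q_cut <- 0
      cfg$cont_weights[["diag"]] <- 0
    },
    "ce+ortho+diag" = {
      cfg$loss_weights[["kl"]] <- 0
      cfg$q_cut <- 0
      cfg$cont_weights[["diag"]] <- dg
    },
    "hce+ortho+diag" = {
      cfg$loss_weights[["kl"]] <- 0
    },
    "KL+hce+ortho" = {
      cfg$cont_weights[["diag"]] <- 0
    },
    "no_distance" = {
      cfg$tie_weights <- FALSE
    },
    "no_distance+corners" = {
      cfg$tie_weights <- FALSE
      cfg$zero_corners <- FALSE
    },
    "full" = NULL)
  cfg$ablation <- mode
  cfg
}

#' Run the full clustering pipeline
#'
#' preprocess (filter, normalize, HVG, PCA) -> spot graph with sigma
#' calibration -> adaptive graph convolution pre-clustering -> virtual
#' image -> DCF pre-training on the pseudo-labels -> self-supervised DCF
#' training -> metrics (and, optionally, spatially variable genes).
#'
#' @param d a \linkS4class{SpotDataset}, or a path readable by
#'   \code{\link{loadSpotDataset}}.
#' @param n_clusters pre-specified cluster number.
#' @param cfg a \code{\link{trainConfig}} /
#'   \code{\link{ablationConfig}} list; NULL builds the platform default.
#' @param n_hvg highly variable genes (default 3000, clipped).
#' @param n_pcs_graph PCs feeding the graph stage (default 50).
#' @param n_pcs_image image channels (default 15).
#' @param sigma_target mean excess adjacency row sum (default 0.5).
#' @param out_dir if non-NULL, labels, traces and reports are written
#'   there as CSV.
#' @param svg if TRUE, run SVG detection per final domain.
#' @param verbose log stage progress.
#' @return list with the dataset, graph, precluster result, image, train
#'   result, final 0-based `labels`, and `ari` (pre/final, when planted
#'   labels exist).
#' @export
runPipeline <- function(d, n_clusters, cfg = NULL, n_hvg = 3000,
                        n_pcs_graph = 50, n_pcs_image = 15,
                        sigma_target = 0.5, out_dir = NULL, svg = FALSE,
                        verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  if (is.character(d)) d <- loadSpotDataset(d, platform = "visium")
  platform <- platformOf(d)
  if (is.null(cfg)) cfg <- trainConfig(platform, n_clusters)

  d <- filterSpots(d)
  d <- normalizeSpots(d)
  d <- selectHVG(d, n_hvg)
  k_graph <- min(n_pcs_graph, length(metadata(d)$hvg_index) - 1L, ncol(d) - 1L)
  k_img <- min(n_pcs_image, k_graph)
  p50 <- fitPCA(d, k_graph, "hvg")
  p15 <- fitPCA(d, k_img, "hvg")
  say("preprocess: %d genes x %d spots, %d HVGs (%.1fs)", nrow(d), ncol(d),
      length(metadata(d)$hvg_index), as.numeric(Sys.time() - t0, "secs"))

  graph <- buildSpotGraph(d, target = sigma_target)
  say("graph: sigma = %.4g", graphSigma(graph))

  pre <- runAGC(pcaScores(p50), laplacian(graph), n_clusters,
                seed = cfg$seed)
  say("precluster: adopted t = %d, %d clusters", pre@stop_t,
      length(unique(preLabels(pre))))

  img <- buildVirtualImage(d, p15)
  params <- dcfInit(k_img, n_clusters, platform, hidden = cfg$hidden,
                    seed = cfg$seed, tie_weights = cfg$tie_weights,
                    zero_corners = cfg$zero_corners)
  pt <- pretrainDcf(params, img, preLabels(pre), cfg)
  say("pretrain: %d iterations (%s)", pt$stopped_at, pt$reason)
  tr <- trainDcf(pt$params, img, preLabels(pre), cfg)
  say("train: %d iterations (%s)", tr$stopped_at, tr$reason)

  labels <- tr$labels
  ari <- NULL
  if (!is.null(colData(d)$true_domain)) {
    truth <- trueDomains(d)
    ari <- c(precluster = ariScore(truth, preLabels(pre)),
             final = ariScore(truth, labels))
    say("ARI: precluster %.3f, final %.3f", ari[1], ari[2])
  }
  svg_tab <- NULL
  if (svg) {
    svg_tab <- do.call(rbind, lapply(sort(unique(labels)), function(dom)
      detectSVG(d, labels, dom)))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(data.frame(spot_id = spotIds(d), label = labels),
                     file.path(out_dir, "labels.csv"), row.names = FALSE)
    utils::write.csv(data.frame(spot_id = spotIds(d),
                                label = preLabels(pre)),
                     file.path(out_dir, "precluster_labels.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(t = seq_along(intraTrace(pre)),
                                intra = intraTrace(pre)),
                     file.path(out_dir, "intra_trace.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(tr$traces),
                     file.path(out_dir, "loss_traces.csv"),
                     row.names = FALSE)
    if (!is.null(ari))
      utils::write.csv(data.frame(stage = names(ari), ari = as.numeric(ari)),
                       file.path(out_dir, "ari.csv"), row.names = FALSE)
    if (!is.null(svg_tab))
      utils::write.table(svg_tab, file.path(out_dir, "svg.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(list(dataset = d, graph = graph, precluster = pre, image = img,
                 pretrain = pt, train = tr, labels = labels, ari = ari,
                 svg = svg_tab, config = cfg))
}

#' Read / write a run configuration as JSON
#'
#' @param path JSON file.
#' @return the configuration list.
#' @export
readRunConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("loss_weights", "cont_weights"))
    if (!is.null(cfg[[nm]])) cfg[[nm]] <- unlist(cfg[[nm]])
  cfg
}

#' @rdname readRunConfig
#' @param cfg configuration list.
#' @export
writeRunConfig <- function(cfg, path) {
  for (nm in c("loss_weights", "cont_weights"))   # keep names in JSON
    if (!is.null(cfg[[nm]])) cfg[[nm]] <- as.list(cfg[[nm]])
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
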