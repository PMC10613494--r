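# Shared end-to-end pipeline fixture on the decoy phantom: files in, report
# out. The seed/cut configuration plays the role of the interactive user: a
# seed in the atrial blood pool, an appendage-orifice cut, and
# pulmonary-vein cuts at the ostia (atrial volumetry conventionally
# excludes both).
pipeline_case <- function() {
  cached("pipeline_case", {
    ph <- decoy_phantom()
    dir <- file.path(tempdir(), "atrialign-pipeline")
    dir.create(dir, showWarnings = FALSE)
    write_flow(ph$flow, file.path(dir, "flow"))
    write_volume(ph$ce, file.path(dir, "ce.nii.gz"))
    write_mask(ph$truth$la_mask_flow, file.path(dir, "ref.nii.gz"))
    tt <- ph$truth$transform
    w <- function(p) as.numeric(apply_rigid(tt, p))
    la_seed <- w(c(0, 0, 0))
    geom <- atrialign:::phantom_geometry(phantom_spec())
    cuts <- list(list(plane_point = w(c(27, 8, 5)),
                      plane_normal = w(geom$laa_center) - la_seed,
                      keep_point = la_seed))
    for (k in 1:4) cuts[[k + 1]] <- list(
      plane_point = w(geom$pv_anchors[k, ]),
      plane_normal = w(geom$pv_anchors[k, ] + geom$pv_dirs[k, ]) -
        w(geom$pv_anchors[k, ]),
      keep_point = la_seed)
    list(dir = dir, config = list(
      flow_prefix = file.path(dir, "flow"),
      ce_mra = file.path(dir, "ce.nii.gz"),
      seeds = list(LA = seed_spec(la_seed, 0.65, 1.35, "LA")),
      seed = 17, rounds = 2,
      reference_mask = file.path(dir, "ref.nii.gz"),
      cuts = cuts, out_dir = file.path(dir, "out")))
  })
}

pipeline_report <- function() {
  cached("pipeline_report", run_pipeline(pipeline_case()$config))
}

# identical configuration into a second output directory (determinism check)
pipeline_report_rerun <- function() {
  cached("pipeline_report_rerun", {
    cfg <- pipeline_case()$config
    cfg$out_dir <- file.path(pipeline_case()$dir, "out2")
    run_pipeline(cfg)
  })
}

report_bytes <- function(out_dir) {
  f <- file.path(out_dir, "report.json")
  readBin(f, "raw", file.size(f))
}
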