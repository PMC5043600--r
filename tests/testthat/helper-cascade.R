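# the hand-built 12-site cascade world ships with the package
cascade_fixture <- function() demo_cascade_cohort()

# acceptance-scale cohorts (cached; heavier than the tiny fixture) --------

acc_sim <- function() cached("acc_sim", simulate_dataset(sim_config(seed = 1L)))

acc_result <- function() cached("acc_result", {
  sim <- acc_sim()
  suppressMessages(run_pipeline(sim$pileup, sim$meta, sim_annotations(sim),
                                sim_pipeline_config(sim$config)))
})

# 30-cell depth-titration cohort: depth is the only varied factor
depth_cfg <- function()
  sim_config(seed = 1L, stages = c("oocyte", "zygote", "2cell"),
             embryos_per_stage = 5L, cells_per_embryo = 2L,
             depth_range = c(1, 4), activity_noise_sd = 0)

depth_result <- function() cached("depth_result", {
  sim <- simulate_dataset(depth_cfg())
  list(sim = sim,
       res = suppressMessages(run_pipeline(sim$pileup, sim$meta,
                                           sim_annotations(sim),
                                           sim_pipeline_config(sim$config))))
})

# 36-cell cohort (6 per stage) for the stage-trajectory rank-sum tests
stage_cfg <- function() sim_config(seed = 1L, embryos_per_stage = 3L)

stage_result <- function() cached("stage_result", {
  sim <- simulate_dataset(stage_cfg())
  list(sim = sim,
       res = suppressMessages(run_pipeline(sim$pileup, sim$meta,
                                           sim_annotations(sim),
                                           sim_pipeline_config(sim$config))))
})
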