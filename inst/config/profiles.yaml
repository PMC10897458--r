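# Versioned clustering profiles.  Every field can be overridden per call or
# from the command line; names follow the pipeline's hyperparameter names
# (investigate_min_sample, radius_ratio, rough_min_points, final_min_points,
# filter_mode).  All post-standardization parameters are unitless.
version: 1
profiles:
  default:
    initial_model: auto        # auto | dbscan | hdbscan (auto: < 1500 points
                               # per standardized area -> dbscan)
    eps: 0.1                   # initial DBSCAN radius, standardized units
    min_samples: 10
    min_cluster_size: 100      # HDBSCAN
    cluster_selection_epsilon: 0.03
    investigate_min_sample: 50 # temporal-refinement seed DBSCAN min_samples
    radius_ratio: 1.96         # multiplier on the SEM inside the search range
    rough_min_points: 50       # region size floor before refinement
    final_min_points: 50       # cluster size floor after refinement
    filter_mode: strict        # strict | lose | none
    static: false
  simulation:                  # uniform simulated noise has no docking clumps,
    inherits: default          # so seed detection can be less conservative
    investigate_min_sample: 25
  isotropic:                   # admit the low-density rim of spherulites
    inherits: simulation
    eps: 0.15
    min_samples: 5
    cluster_selection_epsilon: 0.05
  steric:
    inherits: simulation
  fibril:                      # small, thin, low-density structures
    inherits: simulation
    initial_model: hdbscan
    min_cluster_size: 60
    min_samples: 30
    cluster_selection_epsilon: 0.0
    radius_ratio: 1.0
    rough_min_points: 50
    pdist_max: 30              # search range at the inter-step scale of
                               # filaments (see the methods vignette)
    seed_chain: 3              # filament interior points have 2 neighbors;
                               # seeds chain rather than form dense cores
  sparse-25:                   # nanostructure regime: static 2D clustering
    inherits: default
    static: true
    min_samples: 10
    rough_min_points: 6
    final_min_points: 6
    investigate_min_sample: 10
  sparse-15:
    inherits: sparse-25
    min_samples: 7
  sparse-8:
    inherits: sparse-25
    min_samples: 5
  sparse-4:
    inherits: sparse-25
    min_samples: 3
    rough_min_points: 4
    final_min_points: 4
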