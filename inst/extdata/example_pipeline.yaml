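# Annotated pipeline configuration for hpbbench::run_pipeline().
# All keys are optional; the values below are the defaults.

label: example            # free-text scenario label (recorded in manifest)
seed: 42                  # master seed when simulating a registry

# Path to an existing registry CSV (schema: see ?write_registry).
# Leave null to simulate the default national-audit emulation instead;
# the simulated registry is then written to <out>/registry.csv.
registry: null

years: [2014, 2021]       # simulated registry year range (inclusive)
window: [2020, 2021]      # benchmark window

# total volumes at which detectable differences are tabulated
volumes: [20, 40, 50, 100, 200]

scenarios:
  deltas: [0.02, 0.05, 0.15]    # absolute shifts (proportions)
  twofold: true                 # add the two-fold-benchmark scenario
                                # (adverse indicators only)
  pooling_years: [1, 2, 3, 5, 8]

funnel:
  level: 0.95             # prediction level
  method: exact           # exact (binomial) or normal
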