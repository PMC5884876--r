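step_index,phase,workload,workload_units,duration_min,lactate_mM,hr_bpm,rpe,decision,timestamp_min
0,warmup,3.10,m/s,8,2.10,138.2,3.6,warmup_settled,9
1,adaptation,3.45,m/s,4,2.22,146.0,4.1,threshold_adaptation,13
2,fine_adaptation,3.60,m/s,4,2.28,150.1,4.3,increase_0.15,17
3,fine_adaptation,3.75,m/s,4,2.35,154.0,4.5,increase_0.15,21
4,fine_adaptation,3.90,m/s,4,2.41,157.8,4.7,increase_0.15,25
5,fine_adaptation,4.05,m/s,4,3.32,161.9,4.9,increase_0.15,29
6,verification,3.95,m/s,4,3.30,159.6,4.8,reduce_verify,33
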