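component,feed,solvent,extract,wastewater
water,0.9929,0,0.0616,0.9986
acetic_acid,0.0014,0,0.0019,0.0012
butyric_acid,0.0058,0.0001,0.0558,0
octyl_acetate,0,0.9999,0.8807,0.0001
flow,545.3,49.3,55.9,538.7
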