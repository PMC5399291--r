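taxon,reliance,trend,lo,hi,endemic
Bar-tailed godwit (menzbieri),1.00,-0.061,-0.087,-0.037,TRUE
Far eastern curlew,0.95,-0.058,-0.070,-0.046,TRUE
Curlew sandpiper,0.90,-0.075,-0.095,-0.055,FALSE
Great knot,0.90,-0.051,-0.075,-0.025,TRUE
Red knot,0.90,-0.044,-0.066,-0.022,FALSE
Lesser sand plover,0.70,-0.060,-0.102,-0.020,FALSE
Bar-tailed godwit (baueri),0.50,-0.014,-0.022,-0.006,TRUE
Terek sandpiper,0.40,-0.023,-0.067,0.020,FALSE
Red-necked stint,0.35,-0.016,-0.031,0.000,TRUE
Grey-tailed tattler,0.03,0.011,-0.021,0.041,TRUE
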