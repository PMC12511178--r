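model,role,biomass,glucose,fructose,sucrose,urea,ethanol
mechanistic,train,1.27,2.55,2.93,2.87,0.42,1.69
hybrid,train,0.22,1.49,1.94,0.95,0.68,0.87
mechanistic,test,2.27,4.69,7.50,7.27,0.72,11.14
hybrid,test,0.48,3.61,4.55,5.32,0.43,2.80
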