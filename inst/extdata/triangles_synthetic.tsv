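exposure	mediator	outcome
carb1	cytokine1	homa_ir
carb1	cytokine2	homa_ir
carb2	cytokine1	homa_ir
carb2	cytokine2	bmi
carb3	cytokine3	hdl
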