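pattern	class
introduction	INTRODUCTION
introduction and motivation	INTRODUCTION
motivation	INTRODUCTION
overview	INTRODUCTION
background	BACKGROUND
related work	BACKGROUND
related works	BACKGROUND
previous work	BACKGROUND
prior work	BACKGROUND
literature review	BACKGROUND
state of the art	BACKGROUND
method	METHODS_MATERIALS
methods	METHODS_MATERIALS
methodology	METHODS_MATERIALS
materials	METHODS_MATERIALS
material	METHODS_MATERIALS
materials and methods	METHODS_MATERIALS
material and methods	METHODS_MATERIALS
methods and materials	METHODS_MATERIALS
experimental procedures	METHODS_MATERIALS
experimental procedure	METHODS_MATERIALS
experimental setup	METHODS_MATERIALS
experimental design	METHODS_MATERIALS
study design	METHODS_MATERIALS
patients and methods	METHODS_MATERIALS
subjects and methods	METHODS_MATERIALS
implementation	METHODS_MATERIALS
model	METHODS_MATERIALS
results	RESULTS_DISCUSSION
result	RESULTS_DISCUSSION
discussion	RESULTS_DISCUSSION
results and discussion	RESULTS_DISCUSSION
discussion and results	RESULTS_DISCUSSION
findings	RESULTS_DISCUSSION
evaluation	RESULTS_DISCUSSION
evaluation results	RESULTS_DISCUSSION
experiments	RESULTS_DISCUSSION
experimental results	RESULTS_DISCUSSION
analysis	RESULTS_DISCUSSION
conclusion	CONCLUSIONS_FUTURE
conclusions	CONCLUSIONS_FUTURE
concluding remarks	CONCLUSIONS_FUTURE
future work	CONCLUSIONS_FUTURE
future directions	CONCLUSIONS_FUTURE
conclusions and future work	CONCLUSIONS_FUTURE
conclusion and future work	CONCLUSIONS_FUTURE
summary and conclusions	CONCLUSIONS_FUTURE
outlook	CONCLUSIONS_FUTURE
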