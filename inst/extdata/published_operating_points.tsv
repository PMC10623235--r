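dataset	prevalence	instrument	youden	sensitivity	specificity	ppv	npv
PROACTIVE-CV	0.302	PHQ-2>=2	0.744	0.932	0.812	0.682	0.965
PROACTIVE-CV	0.302	PHQ-2>=3	0.725	0.832	0.893	0.770	0.925
PROACTIVE-CV	0.302	phq2&4>=0.322	0.744	0.907	0.837	0.706	0.954
PROACTIVE-CV	0.302	phq2&8>=0.306	0.769	0.926	0.843	0.719	0.963
PROACTIVE-test	0.302	PHQ-2>=2	0.753	0.934	0.819	0.690	0.966
PROACTIVE-test	0.302	PHQ-2>=3	0.739	0.849	0.890	0.769	0.932
PROACTIVE-test	0.302	phq2&4>=0.322	0.749	0.915	0.834	0.705	0.958
PROACTIVE-test	0.302	phq2&8>=0.306	0.735	0.907	0.828	0.695	0.954
PNS2013	0.084	PHQ-2>=2	0.813	0.927	0.886	0.428	0.993
PNS2013	0.084	PHQ-2>=3	0.749	0.784	0.965	0.674	0.980
PNS2013	0.084	phq2&4>=0.322	0.800	0.859	0.941	0.572	0.986
PNS2013	0.084	phq2&8>=0.306	0.769	0.840	0.930	0.522	0.984
PNS2019	0.105	PHQ-2>=2	0.808	0.942	0.866	0.450	0.992
PNS2019	0.105	PHQ-2>=3	0.756	0.793	0.963	0.716	0.976
PNS2019	0.105	phq2&4>=0.322	0.808	0.872	0.937	0.616	0.984
PNS2019	0.105	phq2&8>=0.306	0.772	0.859	0.914	0.537	0.982
Amazonas	0.192	PHQ-2>=2	0.656	0.891	0.765	0.474	0.967
Amazonas	0.192	PHQ-2>=3	0.640	0.751	0.889	0.617	0.938
Amazonas	0.192	phq2&4>=0.322	0.684	0.834	0.850	0.569	0.956
Amazonas	0.192	phq2&8>=0.306	0.674	0.827	0.847	0.562	0.954
SaoPaulo-Manaus	0.085	PHQ-2>=2	0.766	0.906	0.860	0.375	0.990
SaoPaulo-Manaus	0.085	PHQ-2>=3	0.755	0.821	0.934	0.536	0.982
SaoPaulo-Manaus	0.085	phq2&4>=0.322	0.719	0.829	0.890	0.411	0.982
SaoPaulo-Manaus	0.085	phq2&8>=0.306	0.776	0.889	0.887	0.423	0.989
MexMedStudents	0.249	PHQ-2>=2	0.463	0.906	0.557	0.403	0.947
MexMedStudents	0.249	PHQ-2>=3	0.492	0.557	0.935	0.738	0.865
MexMedStudents	0.249	phq2&4>=0.322	0.623	0.755	0.868	0.653	0.915
MexMedStudents	0.249	phq2&8>=0.306	0.649	0.781	0.868	0.661	0.923
JoyAge	0.192	PHQ-2>=2	0.452	0.958	0.494	0.310	0.980
JoyAge	0.192	PHQ-2>=3	0.595	0.822	0.773	0.462	0.948
JoyAge	0.192	phq2&4>=0.322	0.590	0.915	0.675	0.400	0.971
JoyAge	0.192	phq2&8>=0.306	0.535	0.841	0.695	0.395	0.948
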