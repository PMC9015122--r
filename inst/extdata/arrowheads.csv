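token,notation,class,role
Arrow,WP,DirectedInteraction,spine
TBar,WP,Inhibition,spine
mim-conversion,MIM,Conversion,spine
mim-inhibition,MIM,Inhibition,spine
mim-catalysis,MIM,Catalysis,regulator
mim-stimulation,MIM,Stimulation,regulator
mim-necessary-stimulation,MIM,Stimulation,regulator
mim-binding,MIM,Binding,spine
mim-transcription-translation,MIM,TranscriptionTranslation,spine
mim-modification,MIM,DirectedInteraction,spine
mim-cleavage,MIM,DirectedInteraction,spine
sbgn-inhibition,SBGN,Inhibition,spine
sbgn-catalysis,SBGN,Catalysis,regulator
sbgn-production,SBGN,Conversion,spine
sbgn-stimulation,SBGN,Stimulation,regulator
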