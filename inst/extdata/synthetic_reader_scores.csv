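case,series,metric,reader,score,rank
c01,bsrem_full,image_quality,r1,4,2
c01,dle_standard_f100,image_quality,r1,5,1
c01,osem_f100,image_quality,r1,3,3
c01,bsrem_full,image_quality,r2,4,1
c01,dle_standard_f100,image_quality,r2,4,1
c01,osem_f100,image_quality,r2,2,3
c02,bsrem_full,image_quality,r1,3,2
c02,dle_standard_f100,image_quality,r1,4,1
c02,osem_f100,image_quality,r1,2,3
c02,bsrem_full,image_quality,r2,4,2
c02,dle_standard_f100,image_quality,r2,5,1
c02,osem_f100,image_quality,r2,3,3
c01,bsrem_full,noise_level,r1,4,1
c01,dle_standard_f100,noise_level,r1,4,1
c01,osem_f100,noise_level,r1,2,3
c01,bsrem_full,noise_level,r2,3,2
c01,dle_standard_f100,noise_level,r2,5,1
c01,osem_f100,noise_level,r2,2,3
c02,bsrem_full,noise_level,r1,3,2
c02,dle_standard_f100,noise_level,r1,5,1
c02,osem_f100,noise_level,r1,1,3
c02,bsrem_full,noise_level,r2,4,2
c02,dle_standard_f100,noise_level,r2,5,1
c02,osem_f100,noise_level,r2,2,3
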