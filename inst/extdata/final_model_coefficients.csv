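season,predictor,estimate,lower90,upper90,p_value
winter,(Intercept),-7.76e1,-3.27e2,1.42e2,0.52
winter,feedwater,3.09e-3,2.53e-3,3.99e-3,<0.001
winter,elevation,2.16e-1,-4.14e-1,9.36e-1,0.53
winter,elevation2,-1.63e-4,-6.79e-4,2.88e-4,0.51
winter,distfeed,7.19e-4,-3.69e-4,1.98e-3,0.36
winter,distfeed2,2.13e-7,-7.15e-7,1.01e-6,0.71
winter,distfence,-7.68e-3,-1.34e-2,-1.68e-3,0.07
winter,distfence2,4.30e-5,1.72e-5,6.81e-5,0.02
winter,TPI,-5.99e-2,-1.32e0,1.53e0,0.94
spring,(Intercept),-8.68e1,-2.50e2,6.19e1,0.37
spring,feedwater,1.84e-3,1.52e-3,2.15e-3,<0.001
spring,elevation,2.42e-1,-1.88e-1,7.17e-1,0.39
spring,elevation2,-1.82e-4,-5.22e-4,1.27e-4,0.36
spring,distfeed,3.12e-3,2.08e-3,4.10e-3,<0.001
spring,distfeed2,-1.20e-6,-1.90e-6,-4.36e-7,0.01
spring,distfence,2.70e-3,-2.32e-3,8.54e-3,0.44
spring,distfence2,-2.73e-5,-5.25e-5,-4.67e-6,0.07
spring,TPI,-5.70e-2,-1.06e0,1.09e0,0.92
summer,(Intercept),6.52e1,-2.54e2,4.10e2,0.67
summer,feedwater,2.19e-3,1.51e-3,2.97e-3,<0.001
summer,elevation,-2.30e-1,-1.22e0,6.84e-1,0.60
summer,elevation2,1.82e-4,-4.71e-4,8.82e-4,0.56
summer,distfeed,-2.92e-4,-7.15e-4,2.09e-4,0.30
summer,distfence,1.16e-2,2.78e-3,2.14e-2,0.04
summer,distfence2,-6.45e-5,-1.04e-4,-2.78e-5,0.01
summer,TPI,-2.84e0,-4.52e0,-1.22e0,0.003
autumn,(Intercept),6.36e2,3.47e2,8.88e2,<0.001
autumn,feedwater,-6.93e-4,-1.52e-3,2.66e-5,0.05
autumn,elevation,-1.86e0,-2.58e0,-1.04e0,<0.001
autumn,elevation2,1.35e-3,7.59e-4,1.86e-3,<0.001
autumn,distfeed,-3.43e-3,-4.83e-3,-1.75e-3,<0.001
autumn,distfeed2,3.02e-6,1.89e-6,3.97e-6,<0.001
autumn,distfence,2.94e-2,2.27e-2,3.63e-2,<0.001
autumn,distfence2,-1.08e-4,-1.36e-4,-7.81e-5,<0.001
autumn,TPI,-4.14e0,-5.48e0,-2.90e0,<0.001
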